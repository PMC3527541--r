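#' Define a genome assembly
#'
#' An assembly is an ordered table of chromosome names and lengths.  It is
#' the denominator of every genome-coverage fraction in the depletion
#' analysis and the coordinate frame for probe tiling and interval
#' simulation.  Coordinates are treated as opaque labels on the declared
#' assembly: no liftover between builds is attempted.
#'
#' @param chromosomes a `data.frame` with columns `chrom` and `length`
#'   (bp), or a named numeric vector of lengths.
#' @param name a label for the assembly (e.g. `"hg18"`).
#' @return an object of class `genome_assembly`.
#' @examples
#' genome_assembly(c(chr1 = 1e6, chr2 = 5e5), name = "toy")
#' @export
genome_assembly <- function(chromosomes, name = "custom") {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes))) {
    chromosomes <- data.frame(chrom = names(chromosomes),
                              length = as.numeric(unname(chromosomes)),
                              stringsAsFactors = FALSE)
  }
  if (!is.data.frame(chromosomes) ||
      !all(c("chrom", "length") %in% names(chromosomes))) {
    stop("`chromosomes` must be a data.frame with columns 'chrom' and 'length'")
  }
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$chrom)) {
    stop("chromosome names must be unique")
  }
  if (nrow(chromosomes) == 0L) stop("assembly has no chromosomes")
  if (any(!is.finite(chromosomes$length) | chromosomes$length <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  structure(list(name = name,
                 chromosomes = chromosomes[, c("chrom", "length")]),
            class = "genome_assembly")
}

#' Read a UCSC-style chrom.sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp, no header.
#'
#' @param path path to the chrom.sizes file.
#' @param name assembly label; defaults to the file name without extension.
#' @return a [genome_assembly()].
#' @export
read_chrom_sizes <- function(path, name = NULL) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           stringsAsFactors = FALSE)
  genome_assembly(tab, name = name)
}

#' Total genome size of an assembly
#' @param assembly a [genome_assembly()].
#' @return total length in bp.
#' @export
genome_size <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  sum(assembly$chromosomes$length)
}

#' Named vector of chromosome lengths
#' @param assembly a [genome_assembly()].
#' @export
chrom_lengths <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  stats::setNames(assembly$chromosomes$length, assembly$chromosomes$chrom)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly '%s': %d chromosomes, %.6g bp>\n",
              x$name, nrow(x$chromosomes), genome_size(x)))
  invisible(x)
}

# Error unless the two objects are on compatible assemblies.  Unbound sets
# (assembly NULL) are compatible with anything: printed coordinate tables
# mix builds, so binding is optional by design.
check_same_assembly <- function(a, b) {
  aa <- if (inherits(a, "feature_set")) a$assembly else a
  bb <- if (inherits(b, "feature_set")) b$assembly else b
  if (!is.null(aa) && !is.null(bb) && !identical(aa$name, bb$name)) {
    stop("assembly mismatch: '", aa$name, "' vs '", bb$name, "'")
  }
  invisible(TRUE)
}
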