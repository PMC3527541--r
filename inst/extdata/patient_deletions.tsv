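sample	deletion_position	enhancer_id	expression_pattern
27	chr12∶16606713–16665783	hs607	hindbrain (rhombencephalon), neural tube
25	chr6∶97375836–97550891	hs676	branchial arch, ear, forebrain, hindbrain
01	chr18∶77008844–77024003	hs775	forebrain
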