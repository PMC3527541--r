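enhancer_id	enhancer_position	bracketing_genes	expression
hs98	chr16∶22684122–22685282	CDR2-HS3ST2	Negative
hs628	chr9∶159657–160780	APOA1	Positive
hs1108	chr9∶128945054–128946417	PBX3-FAM125B	Negative
hs7	chr16∶79026563–79028162	WWOX (intragenic)	Negative
hs445	chr1∶83878319–83879217	LPHN2-FLJ23033	Negative
hs1339	chr9∶92292484–92293889	GADD45G-DIRAS2	Positive
hs205	chr2∶66297527–66299214	Meis1-Spred2	Positive
hs571	chr13∶112793153–112794130	Sox1-1700094C09Rik	Negative
hs808	chr18∶73570346–73571156	Zfp516-Tshz1	Negative
hs809	chr1∶87795192–87796737	Lmo4-Hs2st1	Positive
hs855	chr11∶31989173–31990022	Rcn1-Pax6os1	Positive
hs1387	chr3∶63672828–63674786	Sntn-Thoc7	Positive
hs1592	chr20∶39461549–39463625	Mafb-Top1	Negative
hs1675	chr17∶27994702–27996874	Ssh2(intragenic)	Positive
hs607	chr12∶16,610,045–16,611,936	MGST1-LMO3	Positive
hs676	chr6∶97,544,611–97,545,759	KIAA1900 (intragenic)	Positive
hs775	chr18∶77,010,009–77,010,795	CDR2-HS3ST2	Positive
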