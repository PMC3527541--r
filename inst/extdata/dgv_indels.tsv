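indel_id	indel_position	enhancer_id
Variation_115355	chr2∶66296800–66297653	hs205
Variation_61360	chr13∶112793819–112794660	hs571
Variation_61640	chr18∶73569805–73570587	hs808
Variation_41944	chr18∶73569967–73570384	hs808
Variation_69038	chr1∶87796383–87797017	hs809
Variation_60040	chr11∶31989283–31989466	hs855
Variation_51148	chr3∶63673334–63673795	hs1387
Variation_79198	chr20∶39462401–39462826	hs1592
Variation_90558	chr20∶39462851–39463076	hs1592
Variation_79197	chr20∶39462851–39463026	hs1592
Variation_79196	chr20∶39462951–39463626	hs1592
Variation_60230	chr17∶27995436–27995598	hs1675
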