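cnv_id	cnv_position	enhancer_id
2157	chr16∶22557932–22704521	hs98
11533	chr9∶149481–274606	hs628
1512	chr9∶128944285–128954309	hs1108
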