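cnv_id	cnv_position	enhancer_id
CNVR6795.1	chr16∶79026434–79039202	hs7
CNVR6669.1	chr16∶22551908–22712190	hs98
CNVR230.1	chr1∶83598248–83955219	hs445
CNVR4135.1	chr9∶48710–209354	hs628
CNVR4393.2	chr9∶91963403–92343382	hs1339
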