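species	kd_mM	pka
HPPi		8.94
H2PPi		6.13
MgPPi	0.004	
Mg2PPi	0.60	
KPPi	63	
NaPPi	83	
MgHPPi	0.75	
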