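age	hazard
18	5e-04
35	0.00397989
40	0.013
50	0.016
60	0.014
80	0.014
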