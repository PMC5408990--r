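individual_id	rs249764	rs135311	rs626096
carrier01	0	2	1
carrier02	1	0	1
carrier03	1	0	1
carrier04	1	0	0
carrier05	1	0	0
carrier06	1	0	1
carrier07	0	0	2
carrier08	0	1	2
carrier09	0	0	1
carrier10	0	0	0
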