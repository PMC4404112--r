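category	young	aged
Male gender	954	331
Tracheostomy	308	145
VAP	363	159
TOTAL	1395	533
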