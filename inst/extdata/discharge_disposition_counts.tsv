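category	young	aged
Home	480	66
Inpatient rehabilitation	357	96
LTAC	52	38
Skilled nursing facility	283	193
Other	43	12
Death (as inpatient)	180	128
TOTAL	1395	533
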