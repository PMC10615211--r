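# sample_id=BGC1_pulldown_vs_control_18dpa
accession,protein,localization,ratio,p_value
TRITD3Av1G038460.3,MFP1.2,C,100,1e-17
TRITD1Av1G054690.1,MFP1.1,C,100,1e-17
TRITD3Bv1G047250.3,MFP1.2,C,93.506,1e-17
TRITD1Bv1G062760.3,MFP1.1,C,56.176,1e-17
TRITD7Bv1G229280.2,SBE1.3,C,45.482,1e-17
TRITD6Bv1G086030.1,Brittle1 transporter 1,C,26.309,1e-17
TRITD7Av1G275430.16,SBE1.1,C,11.778,1e-17
TRITD2Bv1G044170.1,Disproportionating enzyme 2,O,3.363,0.0064
TRITD7Bv1G229250.2,SBE1.1,C,2.949,0.0033
TRITD5Bv1G140970.6,Phosphoglucose isomerase,C,2.563,0.0291
TRITD5Bv1G201740.3,Plastidial alpha-glucan phosphorylase,C,2.538,0.0211
TRITD2Av1G048150.2,Disproportionating enzyme 1,C,2.359,0.0428
TRITD7Bv1G038900.1,SS2a,C,2.308,0.0006
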