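case,tcv_reader1,tcv_reader2,tcv_model,count_reader1,count_reader2,count_model
K1,43.1,50.7,74.4,102,115,224
K2,105.8,124.2,88.1,96,99,105
K3,614.7,635.4,603.2,274,178,183
K4,726.6,793.8,530.2,676,755,721
K5,1723.1,1732.5,1622.6,279,177,145
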