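# synthetic fixture; energy: MeV, value: keV/um
energy,value
0.001,8.2361848
0.001350314,7.1949939
0.001823348,6.2854269
0.0024620924,5.4908443
0.0033245979,4.7967101
0.0044892513,4.1903261
0.006061899,3.6605991
0.0081854673,3.1978384
0.011052951,2.7935784
0.014924955,2.4404236
0.020153377,2.1319134
0.027213388,1.8624041
0.036746619,1.6269652
0.049619476,1.4212897
0.067001875,1.241615
0.090473572,1.0846542
0.12216773,0.94753584
0.16496481,0.82775154
0.2227543,0.72310996
0.30078825,0.63169682
0.4061586,0.55183982
0.54844166,0.48207808
0.74056847,0.42113539
1,0.36789686
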