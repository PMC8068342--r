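# synthetic fixture; energy: MeV, value: relative fluence
energy,value
0.001,0.053343425
0.001350314,0.10440486
0.001823348,0.17626573
0.0024620924,0.29032536
0.0033245979,0.47094937
0.0044892513,0.63233521
0.006061899,0.73931159
0.0081854673,0.93042518
0.011052951,1
0.014924955,0.89404218
0.020153377,0.81931278
0.027213388,0.63616037
0.036746619,0.47126029
0.049619476,0.30479312
0.067001875,0.17495923
0.090473572,0.10951771
0.12216773,0.05279993
0.16496481,0.022166633
0.2227543,0.010070423
0.30078825,0.0041144529
0.4061586,0.001335819
0.54844166,0.0004502204
0.74056847,0.00012615906
1,3.5116697e-05
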