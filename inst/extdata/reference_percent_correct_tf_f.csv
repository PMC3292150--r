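subject,spectro_std,imdf,bandpower,fi2,wavelet_db3
1,53.75,53.35,54.01,58.53,58.33
2,80.86,57.5,45.41,58.82,61.62
3,79.13,54.17,54.56,54.37,73.25
4,35.62,59.8,57.84,53.92,50.88
5,70.09,48.4,59.29,64.15,67.19
6,57.88,56.94,50.69,79.17,59.42
7,85.88,55.44,60.55,68.77,68.08
8,69.89,51.24,53.9,64.82,52.77
9,64.06,65.66,61.74,60.63,57.16
10,68.75,58.33,66.41,46.28,54.27
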