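subject,spectro_std,imdf,bandpower,fi2,wavelet_db3
1,82.1,53.2,73.31,62.95,74.43
2,86.27,50.32,62.4,51.75,61.33
3,82.55,54.71,59.49,55.55,62.61
4,75.69,49.79,55.94,63.02,54.82
5,84,55.77,67.53,53.35,75.93
6,86.84,51.52,59.14,57.38,71.46
7,75.88,60.36,57.67,63.11,74.39
8,80.71,51.4,72.22,60.46,72.24
9,88.93,55.47,64.88,65.09,61.36
10,72.86,55.71,62.94,52.44,72.33
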