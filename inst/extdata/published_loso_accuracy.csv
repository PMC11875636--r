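subject,eegconformer,capsulenet,atcnet,bandfocusnet
1,90.08,87.02,89.31,86.26
2,53.04,71.30,60.00,70.43
3,65.83,62.50,70.00,69.17
4,76.22,73.43,74.83,78.32
6,59.84,60.63,61.42,66.14
7,71.82,70.00,70.00,75.45
8,59.23,58.46,58.46,64.62
9,58.78,59.54,58.78,57.25
10,69.77,68.60,73.26,67.44
12,58.12,58.12,60.68,60.68
13,59.41,59.41,56.44,59.41
14,70.45,67.42,72.73,76.52
15,60.31,69.47,61.83,66.41
16,75.61,63.41,78.05,80.49
17,80.28,84.51,83.10,82.39
18,69.91,66.37,73.45,73.45
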