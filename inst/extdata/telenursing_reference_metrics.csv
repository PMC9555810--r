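attribute_id,final_category,category_strength,total_strength,better,worse
1,A,13.79,60.92,61.08,12.57
2,A,13.22,60.63,61.06,10.91
3,A,15.23,60.34,63,12.23
4,A,11.21,61.21,59.59,14.16
5,A,13.79,62.07,60.83,13.95
6,M,4.89,76.44,47.49,56.93
7,O,24.14,72.99,74.03,51.34
8,O,31.32,81.61,80.76,58.31
9,I,14.94,47.41,47.48,13.35
10,I,13.51,47.99,48.07,13.06
11,M,27.3,82.47,35.29,63.24
12,M,25.57,80.46,37.03,63.27
13,O,34.2,83.05,83.98,61.42
14,O,30.46,83.05,82.22,58.6
15,O,31.03,83.62,83.53,59.71
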