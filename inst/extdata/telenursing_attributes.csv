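attribute_id,label
1,Remote education on home safety prevention
2,Teletraining on care skills
3,Remote lectures about disease prevention
4,Remote screening for diseases
5,Distance intervention for disease risk factors
6,Remote monitoring of vital signs and sleep
7,Remote diagnosis of diseases
8,Remote health counseling
9,Remote calls for life needs
10,Remote calls for nursing needs
11,Remote one-button emergency caller
12,Remote emergency assistance arrangement
13,Remote rehabilitation guidance
14,Remote return visits and related health education
15,Regular family visits
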