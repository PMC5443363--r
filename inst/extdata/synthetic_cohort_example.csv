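"ID","Sex","Age_y","Height_cm","Weight_kg","BMI"
"S0001","M",18.273,175.3,99.66,
"S0002","M",3.484,96.4,26.63,
"S0003","F",10.045,123.8,21.3,
"S0004","M",8.986,117.4,26.62,
"S0005","M",2.132,93.7,17.62,
"S0006","M",8.832,118.8,19.08,
"S0007","M",9.772,130.9,24.09,
"S0008","F",19.477,160.7,66.34,
"S0009","M",9.173,120.5,33.82,
"S0010","M",14.191,,,30.74
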