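id,gender,race,age,income,l_1,x_1,y_1,l_2,x_2,y_2,l_3,x_3,y_3
8,1,1,1,1,1.12,1,1.40,0.26,1,1.40,-1.37,1,1.20
16,0,0,0,1,0.46,1,1.00,1.51,1,1.20,0.38,1,1.00
24,1,1,0,1,-1.21,0,1.00,0.76,0,1.60,-1.12,1,3.40
32,0,0,0,1,-0.54,1,1.00,-0.74,1,1.40,0.30,1,1.80
40,0,1,1,1,0.04,1,1.40,0.76,1,3.20,-0.37,1,1.60
48,1,1,0,0,0.54,1,3.20,-1.24,1,1.20,0.63,1,3.20
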