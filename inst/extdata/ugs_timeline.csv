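day,kind,species,value
3,liquid_withdrawal,mass,0.02
7.5,gas_injection,CH4,0.16
7.5,gas_injection,CO2,2.0e-3
9,gas_injection,H2,1.06e-1
9,liquid_withdrawal,mass,0.02
10,liquid_withdrawal,mass,0.02
14,liquid_withdrawal,mass,0.02
15,liquid_withdrawal,mass,0.02
17,water_addition,mass,0.353
17,water_addition,dic,2.4e-3
17,water_addition,ca,1.31e-3
17,water_addition,na,6.0e-4
17,water_addition,mg,4.4e-4
17,water_addition,cl,3.0e-4
17,water_addition,so4,7.0e-4
21,liquid_withdrawal,mass,0.02
28,liquid_withdrawal,mass,0.02
35,liquid_withdrawal,mass,0.02
43,liquid_withdrawal,mass,0.02
50,liquid_withdrawal,mass,0.02
57,liquid_withdrawal,mass,0.02
64,liquid_withdrawal,mass,0.02
71,liquid_withdrawal,mass,0.02
78,liquid_withdrawal,mass,0.02
85,liquid_withdrawal,mass,0.02
92,liquid_withdrawal,mass,0.02
99,liquid_withdrawal,mass,0.02
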