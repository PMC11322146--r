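day,species,phase,value,rel_unc
0,CH4,gas,4.54,0.01
0,CO2,gas,4.58e-2,0.01
7,CO2,gas,3.1e-2,0.05
8,CH4,gas,4.7,0.05
8,CO2,gas,3.3e-2,0.05
9,H2,gas,1.06e-1,0.05
21,CO2,gas,2.7e-2,0.05
105,CH4,gas,4.7,0.05
105,CO2,gas,1.95e-2,0.05
105,H2,gas,7.6e-2,0.05
0,dic,aqueous,2.4e-3,0.05
0,ca,aqueous,1.31e-3,0.05
0,na,aqueous,6.0e-4,0.05
0,mg,aqueous,4.4e-4,0.05
0,cl,aqueous,3.0e-4,0.05
0,so4,aqueous,7.0e-4,0.05
0,fe,aqueous,6.5e-6,0.05
0,ba,aqueous,1.0e-6,0.5
0,acetate,aqueous,0,0.05
0,formate,aqueous,0,0.05
3,dic,aqueous,3.1e-3,0.05
3,ca,aqueous,2.88e-3,0.05
3,cl,aqueous,1.97e-3,0.05
3,so4,aqueous,5.9e-4,0.05
3,acetate,aqueous,1.82e-4,0.05
9,dic,aqueous,4.9e-3,0.05
9,ca,aqueous,4.1e-3,0.05
9,so4,aqueous,3.7e-4,0.05
9,acetate,aqueous,7.0e-4,0.05
9,formate,aqueous,0,0.05
15,so4,aqueous,0,0.05
21,dic,aqueous,6.6e-3,0.05
21,ca,aqueous,4.8e-3,0.05
21,so4,aqueous,0,0.05
21,acetate,aqueous,1.08e-3,0.05
21,formate,aqueous,1.12e-3,0.05
28,dic,aqueous,7.1e-3,0.05
28,ca,aqueous,4.9e-3,0.05
90,formate,aqueous,3.4e-3,0.05
105,dic,aqueous,7.1e-3,0.05
105,ca,aqueous,4.9e-3,0.05
105,so4,aqueous,0,0.05
105,acetate,aqueous,1.74e-3,0.05
105,formate,aqueous,3.1e-3,0.05
105,fe,aqueous,1.83e-4,0.05
105,ba,aqueous,1.95e-5,0.05
105,cl,aqueous,1.97e-3,0.05
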