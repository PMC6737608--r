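factor,kind,prevalence,beta_ave,or_ave,approx_paf,exact_paf,ci_lower,ci_upper
High blood pressure,binary,0.474,1.093,2.98,0.518,0.479,0.451,0.506
Lack of physical activity,binary,0.837,0.501,1.65,0.419,0.355,0.277,0.447
"ApoB/ApoA ratio (tertiles)",multicategory,0.669,0.428,1.53,0.286,0.269,0.222,0.319
"Diet score (tertiles)",multicategory,0.670,0.378,1.46,0.253,0.230,0.182,0.289
"Waist-hip ratio (tertiles)",multicategory,0.670,0.294,1.34,0.197,0.188,0.133,0.253
Smoking,binary,0.224,0.513,1.67,0.115,0.124,0.102,0.149
Cardiac causes,binary,0.049,1.156,3.18,0.057,0.091,0.080,0.102
"Alcohol consumption (3 levels)",multicategory,0.277,0.186,1.20,0.052,0.059,0.034,0.097
Global stress,binary,0.144,0.301,1.35,0.043,0.050,0.026,0.073
Diabetes,binary,0.129,0.148,1.16,0.019,0.024,0.001,0.049
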