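survey,psi,psi_se,gamma,gamma_se,epsilon,epsilon_se,p,p_se
1,0.52,0.15,0.80,0.30,0.78,0.20,0.34,0.04
2,0.50,0.23,0.00,0.00,0.67,0.22,0.34,0.04
3,0.16,0.25,0.90,0.20,0.39,0.49,0.34,0.04
4,0.86,0.16,0.46,1.01,0.49,0.21,0.34,0.04
5,0.51,0.17,0.54,0.31,0.30,0.32,0.34,0.04
6,0.62,0.22,0.52,0.33,0.44,0.25,0.34,0.04
7,0.55,0.20,0.10,0.27,0.27,0.25,0.34,0.04
8,0.44,0.18,0.81,0.22,0.00,0.00,0.34,0.04
9,0.89,0.13,0.00,0.22,0.37,0.19,0.34,0.04
10,0.56,0.16,0.10,0.19,0.64,0.23,0.34,0.04
11,0.24,0.24,0.62,0.21,0.07,0.38,0.34,0.04
12,0.70,0.17,NA,NA,NA,NA,0.34,0.04
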