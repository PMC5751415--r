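ligand,kinase,kd_nM,kd_err_nM
1,PKA,5.9,0.5
1a,PKA,7.9,0.5
1c,PKA,6.4,0.1
1d,PKA,9.2,0.8
1e,PKA,43,4
1,PKCe,0.73,0.06
1a,PKCe,19,8
1c,PKCe,0.4,0.02
1d,PKCe,110,19
1e,PKCe,38,9.5
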