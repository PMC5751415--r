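ligand,site,kind,pka
1,N1,base,9.65
1,C5'OH,acid,8.58
1,C4''OH,acid,7.94
1,C6''OH,acid,6.52
1,C10''OH,acid,7.22
1,C15''O2H,acid,2.98
1a,N1,base,8.22
1a,C5'OH,acid,8.74
1a,C4''OH,acid,7.77
1a,C6''OH,acid,6.51
1a,C10''OH,acid,7.18
1a,C15''O2H,acid,2.98
1c,N1,base,9.37
1c,C5'OH,acid,8.55
1c,C4''OH,acid,7.93
1c,C6''OH,acid,6.52
1c,C10''OH,acid,7.22
1c,C15''O2H,acid,2.98
1d,N1,base,6.2
1d,C5'OH,acid,8.62
1d,C4''OH,acid,7.96
1d,C6''OH,acid,6.73
1d,C10''OH,acid,7.28
1d,C15''O2H,acid,2.98
1e,N1,base,6.2
1e,C5'OH,acid,8.62
1e,C4''OH,acid,7.96
1e,C6''OH,acid,6.73
1e,C10''OH,acid,7.28
1e,C15''O2H,acid,2.98
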