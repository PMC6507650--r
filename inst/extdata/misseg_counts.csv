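condition,replicate,n_missegregating,n_total
WT_YEPRG,1,0,66
GAL1-MAD2_YEPRG,1,2,91
WT_22C,1,0,67
tub2-401_22C,1,6,129
WT_YEPRG,2,0,105
GAL1-MAD2_YEPRG,2,3,132
WT_22C,2,0,140
tub2-401_22C,2,16,238
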