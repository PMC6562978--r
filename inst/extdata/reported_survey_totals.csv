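quantity,value
total_recorded,2228
disturbed,19
n_sessions,6
greenness_pct_HB,35.76
greenness_pct_HH,34.53
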