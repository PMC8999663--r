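parameter,sens_pct,spec_pct
mpr,78,84
tpr,63,84
attenuation,51,86
visual,67,90
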