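subzone,plots_sampled,plots_acceptable,n_obs,age_min,age_max,height_min,height_max
dc,20,20,462,85,170,18.64,30.85
dk,4,4,104,100,160,27.04,40.14
dm,1,1,24,120,120,31.93,31.93
dv,5,2,33,75,90,13.75,16.83
mc,5,3,91,115,220,18.12,24.09
mk,4,2,83,175,240,26.17,32.56
mm,5,5,141,70,255,7.84,40.79
mv,8,8,187,85,175,18.51,28.93
mw,5,5,124,80,155,27.32,33.51
vc,4,4,116,105,225,22.13,36.62
wc,4,4,75,85,105,19.89,27.48
wk,6,6,128,90,130,18.64,32.25
wv,5,4,113,95,215,18.99,32.45
xc,12,12,273,80,220,18.20,33.85
xv,4,4,116,120,165,17.11,27.41
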