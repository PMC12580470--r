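# Published pooled relative-abundance-index (RAI, independent events per
# 100 trap-days) and trail-index estimates for five mammal species from a
# 122-camera paired trail/forest survey in the Bavarian Forest National
# Park, by hunting-effort stratum. rai_* columns are the printed point
# estimates; trail_index is the printed ln((rai_trail+1)/(rai_forest+1)).
species,effort,rai_trail,rai_forest,trail_index
red_deer,high,5.55,7.03,-0.20
wild_boar,high,1.15,3.73,-0.79
roe_deer,high,1.62,3.14,-0.46
lynx,high,1.79,0.15,0.88
red_fox,high,4.28,0.66,1.15
red_deer,medium,7.88,8.54,-0.07
wild_boar,medium,2.77,7.08,-0.76
roe_deer,medium,2.58,4.86,-0.49
lynx,medium,0.92,0.10,0.56
red_fox,medium,5.77,0.53,1.49
red_deer,low,5.95,4.50,0.24
wild_boar,low,2.51,4.09,-0.37
roe_deer,low,2.69,3.29,-0.08
lynx,low,1.10,0.14,0.61
red_fox,low,4.10,0.79,1.05
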