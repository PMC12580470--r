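# Published independent-event counts (5-min independence threshold) for
# the same survey: stratum sums over the 61 trail and 61 forest cameras
# and the printed per-camera means.
species,effort,placement,sum_events,mean_events
red_deer,high,trail,394,6.46
red_deer,high,forest,459,7.78
wild_boar,high,trail,82,1.34
wild_boar,high,forest,241,4.08
roe_deer,high,trail,115,1.89
roe_deer,high,forest,208,3.53
lynx,high,trail,127,2.08
lynx,high,forest,10,0.17
red_fox,high,trail,304,4.98
red_fox,high,forest,44,0.75
red_deer,medium,trail,567,9.30
red_deer,medium,forest,582,9.86
wild_boar,medium,trail,192,3.15
wild_boar,medium,forest,329,5.58
roe_deer,medium,trail,193,3.16
roe_deer,medium,forest,497,8.42
lynx,medium,trail,64,1.05
lynx,medium,forest,7,0.12
red_fox,medium,trail,403,6.61
red_fox,medium,forest,37,0.63
red_deer,low,trail,405,6.64
red_deer,low,forest,285,4.83
wild_boar,low,trail,171,2.80
wild_boar,low,forest,265,4.49
roe_deer,low,trail,201,3.30
roe_deer,low,forest,207,3.51
lynx,low,trail,75,1.23
lynx,low,forest,9,0.15
red_fox,low,trail,279,4.57
red_fox,low,forest,50,0.85
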