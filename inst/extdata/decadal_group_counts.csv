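decade,n_spawning_potential,n_residence,min_recapture_lat
1980s,18,63,2.18
1990s,53,359,0.60
2000s,15,152,5.97
2010s,1,61,22.08
2020s,2,138,16.73
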