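decade,n_released,n_recaptured,n_recaptured_north,n_recaptured_south
1980s,1029,257,176,81
1990s,12837,643,233,410
2000s,8804,999,836,163
2010s,2350,180,118,62
2020s,7168,301,161,140
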