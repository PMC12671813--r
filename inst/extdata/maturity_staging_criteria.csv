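stage,mago,pof_present,ia_pct
immature,Ca,FALSE,
developmental,Ty,FALSE,30
regression,Py,FALSE,60
spawning_capable,Sy,TRUE,20
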