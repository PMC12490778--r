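name,n_items,item_min,item_max,aggregation,score_min,score_max
hapys,26,0,4,sum,0,104
hapys_impact,6,0,3,sum,0,18
acrs_protect,13,0,4,mean,0,4
acrs_monitor,4,0,4,mean,0,4
pcs_p,13,0,4,sum,0,52
wi6r,6,0,4,sum,0,24
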