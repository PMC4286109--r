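cluster,p1,p2,p3,p4,p5,p6
cluster1,0,1,.,.,.,.
cluster2,0,1,.,.,.,.
cluster3,0,1,.,.,.,.
cluster4,0,0,.,.,.,.
cluster5,0,0,.,.,.,.
cluster6,0,0,.,.,.,.
cluster7,.,.,0,1,.,.
cluster8,.,.,0,1,.,.
cluster9,.,.,0,1,.,.
cluster10,.,.,0,0,.,.
cluster11,.,.,0,0,.,.
cluster12,.,.,0,0,.,.
cluster13,.,.,.,.,0,1
cluster14,.,.,.,.,0,1
cluster15,.,.,.,.,0,1
cluster16,.,.,.,.,0,0
cluster17,.,.,.,.,0,0
cluster18,.,.,.,.,0,0
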