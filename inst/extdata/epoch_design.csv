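cluster,p1,p2,p3,p4,p5,p6,p7,p8,p9,p10,p11,p12,p13,p14,p15,p16,p17
cluster1,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
cluster2,0,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
cluster3,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1,1,1
cluster4,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1,1
cluster5,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1,1
cluster6,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1,1
cluster7,0,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1,1
cluster8,0,0,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1
cluster9,0,0,0,0,0,0,0,0,0,1,1,1,1,1,1,1,1
cluster10,0,0,0,0,0,0,0,0,0,0,1,1,1,1,1,1,1
cluster11,0,0,0,0,0,0,0,0,0,0,0,1,1,1,1,1,1
cluster12,0,0,0,0,0,0,0,0,0,0,0,0,1,1,1,1,1
cluster13,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1,1,1
cluster14,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1,1
cluster15,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1
cluster16,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1
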