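cluster,p1,p2,p3,p4
cluster1,0,.,1,1
cluster2,0,0,.,1
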