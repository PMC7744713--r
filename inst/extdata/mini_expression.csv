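gene_id,ctrl,highlight,dark
gA,10,20,5
gB,4,4,4
gC,8,2,0
gD,100,50,100
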