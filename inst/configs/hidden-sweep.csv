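hidden,delay_kind
10,none
30,none
10,axonal
30,axonal
10,dendritic
30,dendritic
10,synaptic
30,synaptic
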