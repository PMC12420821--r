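hidden,delay_kind,span
30,none,0.5
30,none,1
30,none,2
30,none,4
30,axonal,0.5
30,axonal,1
30,axonal,2
30,axonal,4
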