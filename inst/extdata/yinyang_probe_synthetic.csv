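x,y,label
0.05,0.35,yin
0.05,0.425,yin
0.05,0.5,yin
0.05,0.575,yin
0.05,0.65,yin
0.125,0.2,yang
0.125,0.275,yang
0.125,0.35,yin
0.125,0.425,yin
0.125,0.5,yin
0.125,0.575,yin
0.125,0.65,yin
0.125,0.725,yin
0.125,0.8,yin
0.2,0.125,yang
0.2,0.2,yang
0.2,0.275,yin
0.2,0.35,yin
0.2,0.425,dot
0.2,0.5,dot
0.2,0.575,dot
0.2,0.65,yin
0.2,0.725,yin
0.2,0.8,yin
0.2,0.875,yin
0.275,0.125,yang
0.275,0.2,yang
0.275,0.275,yin
0.275,0.35,yin
0.275,0.425,dot
0.275,0.5,dot
0.275,0.575,dot
0.275,0.65,yin
0.275,0.725,yin
0.275,0.8,yin
0.275,0.875,yin
0.35,0.05,yang
0.35,0.125,yang
0.35,0.2,yang
0.35,0.275,yin
0.35,0.35,yin
0.35,0.425,yin
0.35,0.5,dot
0.35,0.575,yin
0.35,0.65,yin
0.35,0.725,yin
0.35,0.8,yin
0.35,0.875,yin
0.35,0.95,yin
0.425,0.05,yang
0.425,0.125,yang
0.425,0.2,yang
0.425,0.275,yang
0.425,0.35,yin
0.425,0.425,yin
0.425,0.5,yin
0.425,0.575,yin
0.425,0.65,yin
0.425,0.725,yin
0.425,0.8,yin
0.425,0.875,yin
0.425,0.95,yin
0.5,0.05,yang
0.5,0.125,yang
0.5,0.2,yang
0.5,0.275,yang
0.5,0.35,yang
0.5,0.425,yang
0.5,0.5,yin
0.5,0.575,yin
0.5,0.65,yin
0.5,0.725,yin
0.5,0.8,yin
0.5,0.875,yin
0.5,0.95,yin
0.575,0.05,yang
0.575,0.125,yang
0.575,0.2,yang
0.575,0.275,yang
0.575,0.35,yang
0.575,0.425,yang
0.575,0.5,yang
0.575,0.575,yang
0.575,0.65,yang
0.575,0.725,yin
0.575,0.8,yin
0.575,0.875,yin
0.575,0.95,yin
0.65,0.05,yang
0.65,0.125,yang
0.65,0.2,yang
0.65,0.275,yang
0.65,0.35,yang
0.65,0.425,yang
0.65,0.5,dot
0.65,0.575,yang
0.65,0.65,yang
0.65,0.725,yang
0.65,0.8,yin
0.65,0.875,yin
0.65,0.95,yin
0.725,0.125,yang
0.725,0.2,yang
0.725,0.275,yang
0.725,0.35,yang
0.725,0.425,dot
0.725,0.5,dot
0.725,0.575,dot
0.725,0.65,yang
0.725,0.725,yang
0.725,0.8,yin
0.725,0.875,yin
0.8,0.125,yang
0.8,0.2,yang
0.8,0.275,yang
0.8,0.35,yang
0.8,0.425,dot
0.8,0.5,dot
0.8,0.575,dot
0.8,0.65,yang
0.8,0.725,yang
0.8,0.8,yin
0.8,0.875,yin
0.875,0.2,yang
0.875,0.275,yang
0.875,0.35,yang
0.875,0.425,yang
0.875,0.5,yang
0.875,0.575,yang
0.875,0.65,yang
0.875,0.725,yin
0.875,0.8,yin
0.95,0.35,yang
0.95,0.425,yang
0.95,0.5,yang
0.95,0.575,yang
0.95,0.65,yang
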