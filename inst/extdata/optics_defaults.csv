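"tissue","wavelength","mua","mus"
1,770,0.017,0.74
1,850,0.019,0.64
2,770,0.004,0.3
2,850,0.004,0.3
3,770,0.018,0.55
3,850,0.021,0.5
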