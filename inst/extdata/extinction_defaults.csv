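"wavelength","HbO","HbR"
770,0.00015,0.000302
850,0.000244,0.000159
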