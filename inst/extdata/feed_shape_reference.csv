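powder,median_esd_um,median_elongation,median_convexity
IM_bark,76.5,0.33,0.85
IM_straw,235.5,0.55,0.84
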