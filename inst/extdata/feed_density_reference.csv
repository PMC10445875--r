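powder,rho_a,rho_p
IM_bark,380,480
IM_straw,190,210
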