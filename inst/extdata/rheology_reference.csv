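powder,mill,biomass,carr_index_pct,compressibility_pct,cohesion_kpa
RBM_bark,RBM,bark,27.3,21.0,0.432
RBM_straw,RBM,straw,27.0,27.0,0.398
SBM_bark,SBM,bark,24.3,17.0,0.490
SBM_straw,SBM,straw,30.0,29.0,0.384
VBM_bark,VBM,bark,27.6,18.0,0.600
VBM_straw,VBM,straw,27.2,30.0,0.431
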