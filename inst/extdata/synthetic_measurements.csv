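sample_id,intensity,cells,efficiency
bhk_lysate_6h,410,1e6,0.8
nf73_lysate_6h,130,1.2e6,0.2
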