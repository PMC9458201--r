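quantity,system,value,uncertainty,units
association_constant,2HP-b-CD,520,32,1/M
association_constant,2-6Me-b-CD,771,51,1/M
diffusion_bound,both,1.9e-10,,m^2/s
diffusion_free,both,3.0e-10,,m^2/s
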