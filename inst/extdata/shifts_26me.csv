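label,delta_free,delta_complex,delta_free_hi,delta_complex_hi,delta_delta_printed
H1,5.35,5.29,5.09,5.03,0.02
H3,4.01,4.00,,,0.01
H5,3.94,3.90,,,0.04
H6,3.91,3.88,,,0.03
H2b,3.72,3.68,,,0.04
H4,3.68,3.67,,,0.01
H6-O-Me,3.59,3.59,,,0.00
H2,3.49,3.44,,,0.05
H2-O-Me,3.41,3.42,,,0.01
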