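gs,adc_ratio
2,0.997
6,0.734
7,0.516
8,0.356
9,0.286
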