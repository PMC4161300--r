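((SH:0.749,SP:0.749):0.502,SL:1.251);
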