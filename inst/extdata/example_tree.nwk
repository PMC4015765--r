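((((((Homo:7,Pan:7):2,Gorilla:9):7,Pongo:16):4,Hylobates:20):9,(Macaca:12,Papio:12):17):11,(Ateles:36,Cebus:36):4);
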