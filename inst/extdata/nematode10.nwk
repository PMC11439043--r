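((Btaurus:0.9,Hsapiens:0.9):0.4,((Celegans:0.45,(Dpachys:0.2,Dcoronatus:0.2):0.3):0.25,(Bxylophilus:0.5,(Predivivus:0.45,(Hmephisto:0.2,Hgingivalis:0.2,Hconsperatus:0.2):0.25):0.15):0.2):0.3);
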