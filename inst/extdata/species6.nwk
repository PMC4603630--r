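((spA:0.3,(spB:0.15,spC:0.2):0.1):0.25,(spD:0.35,(spE:0.1,spF:0.18):0.22):0.08)ROOT;
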