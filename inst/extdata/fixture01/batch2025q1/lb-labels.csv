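variable,label
LBTESTCD,Lab Test Short Name
LBORRES,Result or Finding
LBORNRLO,Reference Range Lower Limit
LBORNRHI,Reference Range Upper Limit
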