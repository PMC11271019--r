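USUBJID,EXTRT,EXDOSE,EXDOSU,EXSTDTC,EXENDTC
SYN01-001,PLACEBO,0,mg,2025-01-30,2025-04-10
SYN01-002,DRUG X,50,mg,2025-01-31,2025-04-11
SYN01-003,DRUG X,50,mg,2025-02-11,2025-04-22
SYN01-004,DRUG X,50,mg,2025-01-10,2025-03-21
SYN01-005,DRUG X,50,mg,2025-01-28,2025-03-11
SYN01-006,DRUG X,50,mg,2025-02-03,2025-04-14
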