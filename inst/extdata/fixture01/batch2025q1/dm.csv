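USUBJID,SUBJID,AGE,SEX,RACE,ARM,COUNTRY,RFSTDTC,RFENDTC
SYN01-001,001,44,M,BLACK OR AFRICAN AMERICAN,Placebo,BEL,2025-01-30,2025-04-10
SYN01-002,002,59,M,ASIAN,Active,BEL,2025-01-31,2025-04-11
SYN01-003,003,37,M,WHITE,Active,BEL,2025-02-11,2025-04-22
SYN01-004,004,57,M,WHITE,Active,BEL,2025-01-10,2025-03-21
SYN01-005,005,64,F,WHITE,Active,BEL,2025-01-28,2025-03-11
SYN01-006,006,35,F,WHITE,Active,BEL,2025-02-03,2025-04-14
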