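USUBJID,VISITNUM,VISIT,SVSTDTC
SYN01-001,1,VISIT 1,2025-01-30
SYN01-001,2,VISIT 2,2025-02-13
SYN01-001,3,VISIT 3,2025-02-27
SYN01-001,4,VISIT 4,2025-03-13
SYN01-001,5,VISIT 5,2025-03-27
SYN01-001,6,VISIT 6,2025-04-10
SYN01-002,1,VISIT 1,2025-01-31
SYN01-002,2,VISIT 2,2025-02-14
SYN01-002,3,VISIT 3,2025-02-28
SYN01-002,4,VISIT 4,2025-03-14
SYN01-002,5,VISIT 5,2025-03-28
SYN01-002,6,VISIT 6,2025-04-11
SYN01-003,1,VISIT 1,2025-02-11
SYN01-003,2,VISIT 2,2025-02-25
SYN01-003,3,VISIT 3,2025-03-11
SYN01-003,4,VISIT 4,2025-03-25
SYN01-003,5,VISIT 5,2025-04-08
SYN01-003,6,VISIT 6,2025-04-22
SYN01-004,1,VISIT 1,2025-01-10
SYN01-004,2,VISIT 2,2025-01-24
SYN01-004,3,VISIT 3,2025-02-07
SYN01-004,4,VISIT 4,2025-02-21
SYN01-004,5,VISIT 5,2025-03-07
SYN01-004,6,VISIT 6,2025-03-21
SYN01-005,1,VISIT 1,2025-01-28
SYN01-005,2,VISIT 2,2025-02-11
SYN01-005,3,VISIT 3,2025-02-25
SYN01-005,4,VISIT 4,2025-03-11
SYN01-006,1,VISIT 1,2025-02-03
SYN01-006,2,VISIT 2,2025-02-17
SYN01-006,3,VISIT 3,2025-03-03
SYN01-006,4,VISIT 4,2025-03-17
SYN01-006,5,VISIT 5,2025-03-31
SYN01-006,6,VISIT 6,2025-04-14
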