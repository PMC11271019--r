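USUBJID,DSCAT,DSDECOD,DSTERM,DSSTDTC
SYN01-001,DISPOSITION EVENT,COMPLETED,COMPLETED,2025-04-10
SYN01-002,DISPOSITION EVENT,COMPLETED,COMPLETED,2025-04-11
SYN01-003,DISPOSITION EVENT,COMPLETED,COMPLETED,2025-04-22
SYN01-004,DISPOSITION EVENT,COMPLETED,COMPLETED,2025-03-21
SYN01-005,DISPOSITION EVENT,ADVERSE EVENT,ADVERSE EVENT,2025-03-11
SYN01-006,DISPOSITION EVENT,COMPLETED,COMPLETED,2025-04-14
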