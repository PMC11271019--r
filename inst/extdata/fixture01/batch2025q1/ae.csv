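USUBJID,AESEQ,AEDECOD,AEBODSYS,AESEV,AESER,AESTDTC,AEENDTC
SYN01-001,1,PRURITUS,SKIN AND SUBCUTANEOUS TISSUE DISORDERS,MILD,N,2025-02-18,2025-02-20
SYN01-001,2,INSOMNIA,PSYCHIATRIC DISORDERS,MODERATE,N,2025-03-04,
SYN01-001,3,DIARRHOEA,GASTROINTESTINAL DISORDERS,MILD,N,2025-03-18,2025-03-31
SYN01-001,4,ARTHRALGIA,MUSCULOSKELETAL DISORDERS,MODERATE,N,2025-03,2025-04-05
SYN01-002,1,HEADACHE,NERVOUS SYSTEM DISORDERS,MILD,N,2025-03-31,2025-04-08
SYN01-003,1,PRURITUS,SKIN AND SUBCUTANEOUS TISSUE DISORDERS,MILD,N,2025-02-28,2025-03-12
SYN01-003,2,DIARRHOEA,GASTROINTESTINAL DISORDERS,MODERATE,N,2025-03-13,
SYN01-004,1,PRURITUS,SKIN AND SUBCUTANEOUS TISSUE DISORDERS,MILD,N,2025-01-16,2025-01-26
SYN01-004,2,VOMITING,GASTROINTESTINAL DISORDERS,MODERATE,N,2025-02,2025-02-12
SYN01-006,1,PRURITUS,SKIN AND SUBCUTANEOUS TISSUE DISORDERS,MILD,N,2025-03-03,2025-03-16
SYN01-006,2,INSOMNIA,PSYCHIATRIC DISORDERS,MILD,N,2025-03-18,2025-03-25
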