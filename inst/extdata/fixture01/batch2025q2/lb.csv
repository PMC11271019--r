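USUBJID,LBSEQ,LBTESTCD,LBTEST,LBORRES,LBORRESU,LBORNRLO,LBORNRHI,VISITNUM,VISIT,LBDTC
SYN01-001,1,ALT,ALT,23.37,U/L,7,40,1,VISIT 1,2025-01-30
SYN01-001,2,BILI,BILI,0.49,mg/dL,0.2,1.2,1,VISIT 1,2025-01-30
SYN01-001,3,CREAT,CREAT,0.98,mg/dL,0.6,1.3,1,VISIT 1,2025-01-30
SYN01-001,4,ALT,ALT,19.05,U/L,7,40,2,VISIT 2,2025-02-13
SYN01-001,5,BILI,BILI,0.37,mg/dL,0.2,1.2,2,VISIT 2,2025-02-13
SYN01-001,6,CREAT,CREAT,1.04,mg/dL,0.6,1.3,2,VISIT 2,2025-02-13
SYN01-001,7,ALT,ALT,21.10,U/L,7,40,3,VISIT 3,2025-02-27
SYN01-001,8,BILI,BILI,0.47,mg/dL,0.2,1.2,3,VISIT 3,2025-02-27
SYN01-001,9,CREAT,CREAT,1.08,mg/dL,0.6,1.3,3,VISIT 3,2025-02-27
SYN01-001,10,ALT,ALT,25.31,U/L,7,40,4,VISIT 4,2025-03-13
SYN01-001,11,BILI,BILI,0.91,mg/dL,0.2,1.2,4,VISIT 4,2025-03-13
SYN01-001,12,CREAT,CREAT,0.80,mg/dL,0.6,1.3,4,VISIT 4,2025-03-13
SYN01-001,13,ALT,ALT,30.21,U/L,7,40,5,VISIT 5,2025-03-27
SYN01-001,14,BILI,BILI,0.45,mg/dL,0.2,1.2,5,VISIT 5,2025-03-27
SYN01-001,15,CREAT,CREAT,0.70,mg/dL,0.6,1.3,5,VISIT 5,2025-03-27
SYN01-001,16,ALT,ALT,31.58,U/L,7,40,6,VISIT 6,2025-04-10
SYN01-001,17,BILI,BILI,0.39,mg/dL,0.2,1.2,6,VISIT 6,2025-04-10
SYN01-001,18,CREAT,CREAT,0.79,mg/dL,0.6,1.3,6,VISIT 6,2025-04-10
SYN01-002,19,ALT,ALT,18.16,U/L,7,40,1,VISIT 1,2025-01-31
SYN01-002,20,BILI,BILI,0.68,mg/dL,0.2,1.2,1,VISIT 1,2025-01-31
SYN01-002,21,CREAT,CREAT,0.83,mg/dL,0.6,1.3,1,VISIT 1,2025-01-31
SYN01-002,22,ALT,ALT,24.86,U/L,7,40,2,VISIT 2,2025-02-14
SYN01-002,23,BILI,BILI,0.63,mg/dL,0.2,1.2,2,VISIT 2,2025-02-14
SYN01-002,24,CREAT,CREAT,0.88,mg/dL,0.6,1.3,2,VISIT 2,2025-02-14
SYN01-002,25,ALT,ALT,23.54,U/L,7,40,3,VISIT 3,2025-02-28
SYN01-002,26,BILI,BILI,0.64,mg/dL,0.2,1.2,3,VISIT 3,2025-02-28
SYN01-002,27,CREAT,CREAT,0.99,mg/dL,0.6,1.3,3,VISIT 3,2025-02-28
SYN01-002,28,ALT,ALT,31.52,U/L,7,40,4,VISIT 4,2025-03-14
SYN01-002,29,BILI,BILI,0.66,mg/dL,0.2,1.2,4,VISIT 4,2025-03-14
SYN01-002,30,CREAT,CREAT,0.74,mg/dL,0.6,1.3,4,VISIT 4,2025-03-14
SYN01-002,31,ALT,ALT,39.30,U/L,7,40,5,VISIT 5,2025-03-28
SYN01-002,32,BILI,BILI,0.69,mg/dL,0.2,1.2,5,VISIT 5,2025-03-28
SYN01-002,33,CREAT,CREAT,0.90,mg/dL,0.6,1.3,5,VISIT 5,2025-03-28
SYN01-002,34,ALT,ALT,27.30,U/L,7,40,6,VISIT 6,2025-04-11
SYN01-002,35,BILI,BILI,0.52,mg/dL,0.2,1.2,6,VISIT 6,2025-04-11
SYN01-002,36,CREAT,CREAT,0.92,mg/dL,0.6,1.3,6,VISIT 6,2025-04-11
SYN01-003,37,ALT,ALT,15.17,U/L,7,40,1,VISIT 1,2025-02-11
SYN01-003,38,BILI,BILI,0.49,mg/dL,0.2,1.2,1,VISIT 1,2025-02-11
SYN01-003,39,CREAT,CREAT,0.91,mg/dL,0.6,1.3,1,VISIT 1,2025-02-11
SYN01-003,40,ALT,ALT,31.27,U/L,7,40,2,VISIT 2,2025-02-25
SYN01-003,41,BILI,BILI,0.55,mg/dL,0.2,1.2,2,VISIT 2,2025-02-25
SYN01-003,42,CREAT,CREAT,0.84,mg/dL,0.6,1.3,2,VISIT 2,2025-02-25
SYN01-003,43,ALT,ALT,26.00,U/L,7,40,3,VISIT 3,2025-03-11
SYN01-003,44,BILI,BILI,0.39,mg/dL,0.2,1.2,3,VISIT 3,2025-03-11
SYN01-003,45,CREAT,CREAT,0.86,mg/dL,0.6,1.3,3,VISIT 3,2025-03-11
SYN01-003,46,ALT,ALT,33.26,U/L,7,40,4,VISIT 4,2025-03-25
SYN01-003,47,BILI,BILI,0.61,mg/dL,0.2,1.2,4,VISIT 4,2025-03-25
SYN01-003,48,CREAT,CREAT,0.93,mg/dL,0.6,1.3,4,VISIT 4,2025-03-25
SYN01-003,49,ALT,ALT,25.73,U/L,7,40,5,VISIT 5,2025-04-08
SYN01-003,50,BILI,BILI,0.53,mg/dL,0.2,1.2,5,VISIT 5,2025-04-08
SYN01-003,51,CREAT,CREAT,0.93,mg/dL,0.6,1.3,5,VISIT 5,2025-04-08
SYN01-003,52,ALT,ALT,34.90,U/L,7,40,6,VISIT 6,2025-04-22
SYN01-003,53,BILI,BILI,0.64,mg/dL,0.2,1.2,6,VISIT 6,2025-04-22
SYN01-003,54,CREAT,CREAT,1.12,mg/dL,0.6,1.3,6,VISIT 6,2025-04-22
SYN01-004,55,ALT,ALT,9.03,U/L,7,40,1,VISIT 1,2025-01-10
SYN01-004,56,BILI,BILI,0.59,mg/dL,0.2,1.2,1,VISIT 1,2025-01-10
SYN01-004,57,CREAT,CREAT,0.91,mg/dL,0.6,1.3,1,VISIT 1,2025-01-10
SYN01-004,58,ALT,ALT,16.99,U/L,7,40,2,VISIT 2,2025-01-24
SYN01-004,59,BILI,BILI,0.57,mg/dL,0.2,1.2,2,VISIT 2,2025-01-24
SYN01-004,60,CREAT,CREAT,1.18,mg/dL,0.6,1.3,2,VISIT 2,2025-01-24
SYN01-004,61,ALT,ALT,18.50,U/L,7,40,3,VISIT 3,2025-02-07
SYN01-004,62,BILI,BILI,0.78,mg/dL,0.2,1.2,3,VISIT 3,2025-02-07
SYN01-004,63,CREAT,CREAT,0.88,mg/dL,0.6,1.3,3,VISIT 3,2025-02-07
SYN01-004,64,ALT,ALT,16.90,U/L,7,40,4,VISIT 4,2025-02-21
SYN01-004,65,BILI,BILI,0.52,mg/dL,0.2,1.2,4,VISIT 4,2025-02-21
SYN01-004,66,CREAT,CREAT,0.62,mg/dL,0.6,1.3,4,VISIT 4,2025-02-21
SYN01-004,67,ALT,ALT,34.31,U/L,7,40,5,VISIT 5,2025-03-07
SYN01-004,68,BILI,BILI,0.66,mg/dL,0.2,1.2,5,VISIT 5,2025-03-07
SYN01-004,69,CREAT,CREAT,1.00,mg/dL,0.6,1.3,5,VISIT 5,2025-03-07
SYN01-004,70,ALT,ALT,39.60,U/L,7,40,6,VISIT 6,2025-03-21
SYN01-004,71,BILI,BILI,0.73,mg/dL,0.2,1.2,6,VISIT 6,2025-03-21
SYN01-004,72,CREAT,CREAT,0.88,mg/dL,0.6,1.3,6,VISIT 6,2025-03-21
SYN01-005,73,ALT,ALT,15.19,U/L,7,40,1,VISIT 1,2025-01-28
SYN01-005,74,BILI,BILI,0.90,mg/dL,0.2,1.2,1,VISIT 1,2025-01-28
SYN01-005,75,CREAT,CREAT,0.86,mg/dL,0.6,1.3,1,VISIT 1,2025-01-28
SYN01-005,76,ALT,ALT,11.90,U/L,7,40,2,VISIT 2,2025-02-11
SYN01-005,77,BILI,BILI,0.36,mg/dL,0.2,1.2,2,VISIT 2,2025-02-11
SYN01-005,78,CREAT,CREAT,0.94,mg/dL,0.6,1.3,2,VISIT 2,2025-02-11
SYN01-005,79,ALT,ALT,36.00,U/L,7,40,3,VISIT 3,2025-02-25
SYN01-005,80,BILI,BILI,0.67,mg/dL,0.2,1.2,3,VISIT 3,2025-02-25
SYN01-005,81,CREAT,CREAT,0.82,mg/dL,0.6,1.3,3,VISIT 3,2025-02-25
SYN01-005,82,ALT,ALT,33.45,U/L,7,40,4,VISIT 4,2025-03-11
SYN01-005,83,BILI,BILI,0.88,mg/dL,0.2,1.2,4,VISIT 4,2025-03-11
SYN01-005,84,CREAT,CREAT,0.59,mg/dL,0.6,1.3,4,VISIT 4,2025-03-11
SYN01-006,85,ALT,ALT,18.65,U/L,7,40,1,VISIT 1,2025-02-03
SYN01-006,86,BILI,BILI,0.47,mg/dL,0.2,1.2,1,VISIT 1,2025-02-03
SYN01-006,87,CREAT,CREAT,0.77,mg/dL,0.6,1.3,1,VISIT 1,2025-02-03
SYN01-006,88,ALT,ALT,23.45,U/L,7,40,2,VISIT 2,2025-02-17
SYN01-006,89,BILI,BILI,0.47,mg/dL,0.2,1.2,2,VISIT 2,2025-02-17
SYN01-006,90,CREAT,CREAT,0.95,mg/dL,0.6,1.3,2,VISIT 2,2025-02-17
SYN01-006,91,ALT,ALT,30.16,U/L,7,40,3,VISIT 3,2025-03-03
SYN01-006,92,BILI,BILI,0.55,mg/dL,0.2,1.2,3,VISIT 3,2025-03-03
SYN01-006,93,CREAT,CREAT,1.12,mg/dL,0.6,1.3,3,VISIT 3,2025-03-03
SYN01-006,94,ALT,ALT,28.96,U/L,7,40,4,VISIT 4,2025-03-17
SYN01-006,95,BILI,BILI,0.77,mg/dL,0.2,1.2,4,VISIT 4,2025-03-17
SYN01-006,96,CREAT,CREAT,1.13,mg/dL,0.6,1.3,4,VISIT 4,2025-03-17
SYN01-006,97,ALT,ALT,30.81,U/L,7,40,5,VISIT 5,2025-03-31
SYN01-006,98,BILI,BILI,0.65,mg/dL,0.2,1.2,5,VISIT 5,2025-03-31
SYN01-006,99,CREAT,CREAT,0.81,mg/dL,0.6,1.3,5,VISIT 5,2025-03-31
SYN01-006,100,ALT,ALT,33.58,U/L,7,40,6,VISIT 6,2025-04-14
SYN01-006,101,BILI,BILI,0.54,mg/dL,0.2,1.2,6,VISIT 6,2025-04-14
SYN01-006,102,CREAT,CREAT,0.64,mg/dL,0.6,1.3,6,VISIT 6,2025-04-14
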