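USUBJID,VSSEQ,VSTESTCD,VSORRES,VSORRESU,VISITNUM,VISIT,VSDTC
SYN01-001,1,SYSBP,103,mmHg,1,VISIT 1,2025-01-30
SYN01-001,2,DIABP,82,mmHg,1,VISIT 1,2025-01-30
SYN01-001,3,PULSE,52,beats/min,1,VISIT 1,2025-01-30
SYN01-001,4,SYSBP,95,mmHg,2,VISIT 2,2025-02-13
SYN01-001,5,DIABP,79,mmHg,2,VISIT 2,2025-02-13
SYN01-001,6,PULSE,85,beats/min,2,VISIT 2,2025-02-13
SYN01-001,7,SYSBP,129,mmHg,3,VISIT 3,2025-02-27
SYN01-001,8,DIABP,73,mmHg,3,VISIT 3,2025-02-27
SYN01-001,9,PULSE,81,beats/min,3,VISIT 3,2025-02-27
SYN01-001,10,SYSBP,129,mmHg,4,VISIT 4,2025-03-13
SYN01-001,11,DIABP,81,mmHg,4,VISIT 4,2025-03-13
SYN01-001,12,PULSE,64,beats/min,4,VISIT 4,2025-03-13
SYN01-001,13,SYSBP,117,mmHg,5,VISIT 5,2025-03-27
SYN01-001,14,DIABP,82,mmHg,5,VISIT 5,2025-03-27
SYN01-001,15,PULSE,66,beats/min,5,VISIT 5,2025-03-27
SYN01-001,16,SYSBP,140,mmHg,6,VISIT 6,2025-04-10
SYN01-001,17,DIABP,76,mmHg,6,VISIT 6,2025-04-10
SYN01-001,18,PULSE,64,beats/min,6,VISIT 6,2025-04-10
SYN01-002,19,SYSBP,139,mmHg,1,VISIT 1,2025-01-31
SYN01-002,20,DIABP,77,mmHg,1,VISIT 1,2025-01-31
SYN01-002,21,PULSE,71,beats/min,1,VISIT 1,2025-01-31
SYN01-002,22,SYSBP,124,mmHg,2,VISIT 2,2025-02-14
SYN01-002,23,DIABP,82,mmHg,2,VISIT 2,2025-02-14
SYN01-002,24,PULSE,74,beats/min,2,VISIT 2,2025-02-14
SYN01-002,25,SYSBP,114,mmHg,3,VISIT 3,2025-02-28
SYN01-002,26,DIABP,77,mmHg,3,VISIT 3,2025-02-28
SYN01-002,27,PULSE,78,beats/min,3,VISIT 3,2025-02-28
SYN01-002,28,SYSBP,129,mmHg,4,VISIT 4,2025-03-14
SYN01-002,29,DIABP,76,mmHg,4,VISIT 4,2025-03-14
SYN01-002,30,PULSE,64,beats/min,4,VISIT 4,2025-03-14
SYN01-002,31,SYSBP,127,mmHg,5,VISIT 5,2025-03-28
SYN01-002,32,DIABP,72,mmHg,5,VISIT 5,2025-03-28
SYN01-002,33,PULSE,90,beats/min,5,VISIT 5,2025-03-28
SYN01-002,34,SYSBP,124,mmHg,6,VISIT 6,2025-04-11
SYN01-002,35,DIABP,78,mmHg,6,VISIT 6,2025-04-11
SYN01-002,36,PULSE,57,beats/min,6,VISIT 6,2025-04-11
SYN01-003,37,SYSBP,119,mmHg,1,VISIT 1,2025-02-11
SYN01-003,38,DIABP,73,mmHg,1,VISIT 1,2025-02-11
SYN01-003,39,PULSE,74,beats/min,1,VISIT 1,2025-02-11
SYN01-003,40,SYSBP,119,mmHg,2,VISIT 2,2025-02-25
SYN01-003,41,DIABP,75,mmHg,2,VISIT 2,2025-02-25
SYN01-003,42,PULSE,76,beats/min,2,VISIT 2,2025-02-25
SYN01-003,43,SYSBP,110,mmHg,3,VISIT 3,2025-03-11
SYN01-003,44,DIABP,83,mmHg,3,VISIT 3,2025-03-11
SYN01-003,45,PULSE,67,beats/min,3,VISIT 3,2025-03-11
SYN01-003,46,SYSBP,134,mmHg,4,VISIT 4,2025-03-25
SYN01-003,47,DIABP,76,mmHg,4,VISIT 4,2025-03-25
SYN01-003,48,PULSE,73,beats/min,4,VISIT 4,2025-03-25
SYN01-003,49,SYSBP,136,mmHg,5,VISIT 5,2025-04-08
SYN01-003,50,DIABP,77,mmHg,5,VISIT 5,2025-04-08
SYN01-003,51,PULSE,82,beats/min,5,VISIT 5,2025-04-08
SYN01-003,52,SYSBP,117,mmHg,6,VISIT 6,2025-04-22
SYN01-003,53,DIABP,75,mmHg,6,VISIT 6,2025-04-22
SYN01-003,54,PULSE,84,beats/min,6,VISIT 6,2025-04-22
SYN01-004,55,SYSBP,124,mmHg,1,VISIT 1,2025-01-10
SYN01-004,56,DIABP,87,mmHg,1,VISIT 1,2025-01-10
SYN01-004,57,PULSE,84,beats/min,1,VISIT 1,2025-01-10
SYN01-004,58,SYSBP,134,mmHg,2,VISIT 2,2025-01-24
SYN01-004,59,DIABP,72,mmHg,2,VISIT 2,2025-01-24
SYN01-004,60,PULSE,95,beats/min,2,VISIT 2,2025-01-24
SYN01-004,61,SYSBP,118,mmHg,3,VISIT 3,2025-02-07
SYN01-004,62,DIABP,67,mmHg,3,VISIT 3,2025-02-07
SYN01-004,63,PULSE,78,beats/min,3,VISIT 3,2025-02-07
SYN01-004,64,SYSBP,110,mmHg,4,VISIT 4,2025-02-21
SYN01-004,65,DIABP,78,mmHg,4,VISIT 4,2025-02-21
SYN01-004,66,PULSE,67,beats/min,4,VISIT 4,2025-02-21
SYN01-004,67,SYSBP,131,mmHg,5,VISIT 5,2025-03-07
SYN01-004,68,DIABP,72,mmHg,5,VISIT 5,2025-03-07
SYN01-004,69,PULSE,72,beats/min,5,VISIT 5,2025-03-07
SYN01-004,70,SYSBP,130,mmHg,6,VISIT 6,2025-03-21
SYN01-004,71,DIABP,80,mmHg,6,VISIT 6,2025-03-21
SYN01-004,72,PULSE,76,beats/min,6,VISIT 6,2025-03-21
SYN01-005,73,SYSBP,102,mmHg,1,VISIT 1,2025-01-28
SYN01-005,74,DIABP,81,mmHg,1,VISIT 1,2025-01-28
SYN01-005,75,PULSE,75,beats/min,1,VISIT 1,2025-01-28
SYN01-005,76,SYSBP,129,mmHg,2,VISIT 2,2025-02-11
SYN01-005,77,DIABP,69,mmHg,2,VISIT 2,2025-02-11
SYN01-005,78,PULSE,67,beats/min,2,VISIT 2,2025-02-11
SYN01-005,79,SYSBP,145,mmHg,3,VISIT 3,2025-02-25
SYN01-005,80,DIABP,86,mmHg,3,VISIT 3,2025-02-25
SYN01-005,81,PULSE,89,beats/min,3,VISIT 3,2025-02-25
SYN01-005,82,SYSBP,107,mmHg,4,VISIT 4,2025-03-11
SYN01-005,83,DIABP,79,mmHg,4,VISIT 4,2025-03-11
SYN01-005,84,PULSE,56,beats/min,4,VISIT 4,2025-03-11
SYN01-006,85,SYSBP,121,mmHg,1,VISIT 1,2025-02-03
SYN01-006,86,DIABP,72,mmHg,1,VISIT 1,2025-02-03
SYN01-006,87,PULSE,64,beats/min,1,VISIT 1,2025-02-03
SYN01-006,88,SYSBP,90,mmHg,2,VISIT 2,2025-02-17
SYN01-006,89,DIABP,73,mmHg,2,VISIT 2,2025-02-17
SYN01-006,90,PULSE,82,beats/min,2,VISIT 2,2025-02-17
SYN01-006,91,SYSBP,131,mmHg,3,VISIT 3,2025-03-03
SYN01-006,92,DIABP,80,mmHg,3,VISIT 3,2025-03-03
SYN01-006,93,PULSE,74,beats/min,3,VISIT 3,2025-03-03
SYN01-006,94,SYSBP,115,mmHg,4,VISIT 4,2025-03-17
SYN01-006,95,DIABP,75,mmHg,4,VISIT 4,2025-03-17
SYN01-006,96,PULSE,72,beats/min,4,VISIT 4,2025-03-17
SYN01-006,97,SYSBP,147,mmHg,5,VISIT 5,2025-03-31
SYN01-006,98,DIABP,83,mmHg,5,VISIT 5,2025-03-31
SYN01-006,99,PULSE,65,beats/min,5,VISIT 5,2025-03-31
SYN01-006,100,SYSBP,129,mmHg,6,VISIT 6,2025-04-14
SYN01-006,101,DIABP,85,mmHg,6,VISIT 6,2025-04-14
SYN01-006,102,PULSE,73,beats/min,6,VISIT 6,2025-04-14
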