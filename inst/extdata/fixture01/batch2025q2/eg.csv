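USUBJID,EGSEQ,EGTESTCD,EGORRES,EGORRESU,VISITNUM,VISIT,EGDTC
SYN01-001,1,QT,426.6,ms,1,VISIT 1,2025-01-30
SYN01-001,2,HR,75.3,beats/min,1,VISIT 1,2025-01-30
SYN01-001,3,QT,404.8,ms,2,VISIT 2,2025-02-13
SYN01-001,4,HR,76.2,beats/min,2,VISIT 2,2025-02-13
SYN01-001,5,QT,393.1,ms,3,VISIT 3,2025-02-27
SYN01-001,6,HR,60.7,beats/min,3,VISIT 3,2025-02-27
SYN01-001,7,QT,399.2,ms,4,VISIT 4,2025-03-13
SYN01-001,8,HR,69.1,beats/min,4,VISIT 4,2025-03-13
SYN01-001,9,QT,436.7,ms,5,VISIT 5,2025-03-27
SYN01-001,10,HR,65.4,beats/min,5,VISIT 5,2025-03-27
SYN01-001,11,QT,389.3,ms,6,VISIT 6,2025-04-10
SYN01-001,12,HR,75.8,beats/min,6,VISIT 6,2025-04-10
SYN01-002,13,QT,401.9,ms,1,VISIT 1,2025-01-31
SYN01-002,14,HR,66.8,beats/min,1,VISIT 1,2025-01-31
SYN01-002,15,QT,405.1,ms,2,VISIT 2,2025-02-14
SYN01-002,16,HR,59.8,beats/min,2,VISIT 2,2025-02-14
SYN01-002,17,QT,401.6,ms,3,VISIT 3,2025-02-28
SYN01-002,18,HR,75.4,beats/min,3,VISIT 3,2025-02-28
SYN01-002,19,QT,431.0,ms,4,VISIT 4,2025-03-14
SYN01-002,20,HR,76.7,beats/min,4,VISIT 4,2025-03-14
SYN01-002,21,QT,409.8,ms,5,VISIT 5,2025-03-28
SYN01-002,22,HR,72.4,beats/min,5,VISIT 5,2025-03-28
SYN01-002,23,QT,388.4,ms,6,VISIT 6,2025-04-11
SYN01-002,24,HR,77.9,beats/min,6,VISIT 6,2025-04-11
SYN01-003,25,QT,408.5,ms,1,VISIT 1,2025-02-11
SYN01-003,26,HR,73.0,beats/min,1,VISIT 1,2025-02-11
SYN01-003,27,QT,422.6,ms,2,VISIT 2,2025-02-25
SYN01-003,28,HR,64.3,beats/min,2,VISIT 2,2025-02-25
SYN01-003,29,QT,399.0,ms,3,VISIT 3,2025-03-11
SYN01-003,30,HR,74.6,beats/min,3,VISIT 3,2025-03-11
SYN01-003,31,QT,385.5,ms,4,VISIT 4,2025-03-25
SYN01-003,32,HR,77.2,beats/min,4,VISIT 4,2025-03-25
SYN01-003,33,QT,408.8,ms,5,VISIT 5,2025-04-08
SYN01-003,34,HR,77.5,beats/min,5,VISIT 5,2025-04-08
SYN01-003,35,QT,390.5,ms,6,VISIT 6,2025-04-22
SYN01-003,36,HR,77.8,beats/min,6,VISIT 6,2025-04-22
SYN01-004,37,QT,377.6,ms,1,VISIT 1,2025-01-10
SYN01-004,38,HR,68.9,beats/min,1,VISIT 1,2025-01-10
SYN01-004,39,QT,403.0,ms,2,VISIT 2,2025-01-24
SYN01-004,40,HR,77.1,beats/min,2,VISIT 2,2025-01-24
SYN01-004,41,QT,400.4,ms,3,VISIT 3,2025-02-07
SYN01-004,42,HR,75.2,beats/min,3,VISIT 3,2025-02-07
SYN01-004,43,QT,405.8,ms,4,VISIT 4,2025-02-21
SYN01-004,44,HR,68.4,beats/min,4,VISIT 4,2025-02-21
SYN01-004,45,QT,403.9,ms,5,VISIT 5,2025-03-07
SYN01-004,46,HR,70.9,beats/min,5,VISIT 5,2025-03-07
SYN01-004,47,QT,403.6,ms,6,VISIT 6,2025-03-21
SYN01-004,48,HR,63.5,beats/min,6,VISIT 6,2025-03-21
SYN01-005,49,QT,398.8,ms,1,VISIT 1,2025-01-28
SYN01-005,50,HR,75.1,beats/min,1,VISIT 1,2025-01-28
SYN01-005,51,QT,400.6,ms,2,VISIT 2,2025-02-11
SYN01-005,52,HR,68.4,beats/min,2,VISIT 2,2025-02-11
SYN01-005,53,QT,404.6,ms,3,VISIT 3,2025-02-25
SYN01-005,54,HR,74.4,beats/min,3,VISIT 3,2025-02-25
SYN01-005,55,QT,388.4,ms,4,VISIT 4,2025-03-11
SYN01-005,56,HR,60.1,beats/min,4,VISIT 4,2025-03-11
SYN01-006,57,QT,404.1,ms,1,VISIT 1,2025-02-03
SYN01-006,58,HR,62.6,beats/min,1,VISIT 1,2025-02-03
SYN01-006,59,QT,373.9,ms,2,VISIT 2,2025-02-17
SYN01-006,60,HR,70.4,beats/min,2,VISIT 2,2025-02-17
SYN01-006,61,QT,406.4,ms,3,VISIT 3,2025-03-03
SYN01-006,62,HR,79.9,beats/min,3,VISIT 3,2025-03-03
SYN01-006,63,QT,401.0,ms,4,VISIT 4,2025-03-17
SYN01-006,64,HR,72.3,beats/min,4,VISIT 4,2025-03-17
SYN01-006,65,QT,406.9,ms,5,VISIT 5,2025-03-31
SYN01-006,66,HR,66.8,beats/min,5,VISIT 5,2025-03-31
SYN01-006,67,QT,379.9,ms,6,VISIT 6,2025-04-14
SYN01-006,68,HR,69.1,beats/min,6,VISIT 6,2025-04-14
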