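batch_id: batch2025q1
cutoff_date: '2025-03-31'
blinded: no
treatment_var: ARM
domains:
  DM: dm.csv
  EX: ex.csv
  SV: sv.csv
  AE: ae.csv
  LB: lb.csv
  EG: eg.csv
  VS: vs.csv
  DS: ds.csv
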