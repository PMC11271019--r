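study:
  study_id: STUDY
  cutoff_date: ~
settings:
  blinded: true
  subject_id_var: USUBJID
  severity_order: [MILD, MODERATE, SEVERE]
data:
  batch_id: current
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
chapters:
  - template: disposition
    output: disposition
    params:
      dataset: DS
  - template: demographics
    output: demographics
    params:
      dataset: DM
      categorical_vars: [SEX, RACE]
      continuous_vars: [AGE]
  - template: adverse_events
    output: adverse-events
    params:
      dataset: AE
      exposure_dataset: EX
      teae_only: true
      lag_days: 30
  - template: labs
    output: labs
    params:
      dataset: LB
      parameters: [ALT, BILI]
      edish: true
profiles:
  page_height_units: 10
  subjects: all
  modules:
    - kind: text
      domain: DM
      title: Demographics
      vars:
        Age: AGE
        Sex: SEX
        Race: RACE
    - kind: interval
      domain: EX
      title: Treatment exposure
      label_var: EXTRT
      start_var: EXSTDTC
      end_var: EXENDTC
    - kind: interval
      domain: AE
      title: Adverse events
      label_var: AEDECOD
      start_var: AESTDTC
      end_var: AEENDTC
    - kind: event
      domain: DS
      title: Disposition
      label_var: DSDECOD
      date_var: DSSTDTC
    - kind: line
      domain: LB
      title: ALT (U/L)
      test_var: LBTESTCD
      parameter: ALT
      value_var: LBORRES
      date_var: LBDTC
      lo_var: LBORNRLO
      hi_var: LBORNRHI
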