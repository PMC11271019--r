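# Default required variables per domain; shipped as configuration, not code
# constants, so studies with non-standard implementations can override.
DM: [USUBJID, AGE, SEX, ARM, RFSTDTC]
AE: [USUBJID, AESEQ, AEDECOD, AEBODSYS, AESEV, AESTDTC]
LB: [USUBJID, LBTESTCD, LBORRES, LBORNRLO, LBORNRHI, LBDTC, VISITNUM]
EG: [USUBJID, EGTESTCD, EGORRES, EGDTC, VISITNUM]
VS: [USUBJID, VSTESTCD, VSORRES, VSDTC, VISITNUM]
EX: [USUBJID, EXTRT, EXSTDTC, EXENDTC]
SV: [USUBJID, VISITNUM, VISIT, SVSTDTC]
DS: [USUBJID, DSDECOD, DSTERM, DSSTDTC]
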