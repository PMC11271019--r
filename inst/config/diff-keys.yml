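# Default record keys per domain for batch-to-batch diffing.
default: [USUBJID]
DM: [USUBJID]
AE: [USUBJID, AEDECOD, AESTDTC, AESEQ]
LB: [USUBJID, LBTESTCD, VISITNUM, LBSEQ]
EG: [USUBJID, EGTESTCD, VISITNUM, EGSEQ]
VS: [USUBJID, VSTESTCD, VISITNUM, VSSEQ]
SV: [USUBJID, VISITNUM]
EX: [USUBJID, EXSTDTC]
DS: [USUBJID, DSDECOD]
CM: [USUBJID, CMTRT, CMSTDTC]
MH: [USUBJID, MHTERM]
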