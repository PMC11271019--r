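variable,label
USUBJID,Unique Subject Identifier
AGE,Age
SEX,Sex
RACE,Race
ARM,Description of Planned Arm
RFSTDTC,Subject Reference Start Date/Time
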