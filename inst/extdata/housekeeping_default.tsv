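symbol
ACTB
GAPDH
B2M
TUBB
TUBA1B
RPL13A
RPL7
RPL10
RPL11
RPL23A
RPS2
RPS3
RPS6
RPS18
RPS27
RPLP0
RPLP1
EEF1A1
EEF2
HPRT1
PGK1
PPIA
TBP
UBC
YWHAZ
SDHA
GUSB
HMBS
POLR2A
LDHA
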