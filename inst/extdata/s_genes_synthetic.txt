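SYN-S-01
SYN-S-02
SYN-S-03
SYN-S-04
SYN-S-05
SYN-S-06
SYN-S-07
SYN-S-08
SYN-S-09
SYN-S-10
SYN-S-11
SYN-S-12
SYN-S-13
SYN-S-14
SYN-S-15
SYN-S-16
SYN-S-17
SYN-S-18
SYN-S-19
SYN-S-20
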