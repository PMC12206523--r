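SYN-G2M-01
SYN-G2M-02
SYN-G2M-03
SYN-G2M-04
SYN-G2M-05
SYN-G2M-06
SYN-G2M-07
SYN-G2M-08
SYN-G2M-09
SYN-G2M-10
SYN-G2M-11
SYN-G2M-12
SYN-G2M-13
SYN-G2M-14
SYN-G2M-15
SYN-G2M-16
SYN-G2M-17
SYN-G2M-18
SYN-G2M-19
SYN-G2M-20
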