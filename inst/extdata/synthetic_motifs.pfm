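>SYN0001 SYN_TATA
A [  1 16  1 16 16  2 ]
C [  1  0  0  0  0  2 ]
G [  1  0  0  0  0 12 ]
T [ 13  0 15  0  0  0 ]
>SYN0002 SYN_GCBOX
A [  0  1  0  0  1  0 ]
C [  2  0 14  2  0 13 ]
G [ 12 13  0 12 13  1 ]
T [  0  0  0  0  0  0 ]
>SYN0003 SYN_PAL
A [ 12  0  1  0 ]
C [  0 11  0  0 ]
G [  0  0 11  0 ]
T [  0  1  0 12 ]
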