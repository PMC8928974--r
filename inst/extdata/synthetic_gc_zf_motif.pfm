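>SYN0001 SYNTH_GC_ZF
A [ 2 0 1 0 16 0 0 1 3 ]
C [ 3 1 17 0 1 0 0 2 14 ]
G [ 12 18 1 19 2 19 18 16 2 ]
T [ 2 0 0 0 0 0 1 0 0 ]
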