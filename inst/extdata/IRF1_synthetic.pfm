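>IRF1_synthetic IRF-E-like synthetic matrix (consensus TTTCACTTTC)
A [  1  1  1  1 97  1  1  1  1  1 ]
C [  1  1  1 97  1 97  1  1  1 97 ]
G [  1  1  1  1  1  1  1  1  1  1 ]
T [ 97 97 97  1  1  1 97 97 97  1 ]
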