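>FOX FoxA1-like forkhead motif (consensus TGTTTAC)
A  [  5  5  5  5  5 85  5 ]
C  [  5  5  5  5  5  5 85 ]
G  [  5 85  5  5  5  5  5 ]
T  [ 85  5 85 85 85  5  5 ]
>ERE_half Estrogen response element half site (consensus AGGTCA)
A  [ 85  5  5  5  5 85 ]
C  [  5  5  5  5 85  5 ]
G  [  5 85 85  5  5  5 ]
T  [  5  5  5 85  5  5 ]
>AP1 AP-1-like TRE motif (consensus TGACTCA)
A  [  5  5 85  5  5  5 85 ]
C  [  5  5  5 85  5 85  5 ]
G  [  5 85  5  5  5  5  5 ]
T  [ 85  5  5  5 85  5  5 ]
>GATA GATA-family motif (consensus AGATAA)
A  [ 85  5 85  5 85 85 ]
C  [  5  5  5  5  5  5 ]
G  [  5 85  5  5  5  5 ]
T  [  5  5  5 85  5  5 ]
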