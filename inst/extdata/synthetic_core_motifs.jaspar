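>Pou5f3 synthetic_pou_octamer_like
A [ 85  2  2  5 88 90 82  3 ]
C [  5  3  4 85  4  3  6  4 ]
G [  5  4 90  5  4  3  6  5 ]
T [  5 91  4  5  4  4  6 88 ]
>Sox19b synthetic_sox_hmg_like
A [ 84 88  3  84  85  4  6 ]
C [  6  4 89   4   5  4  5 ]
G [  5  4  4   6   5  6 84 ]
T [  5  4  4   6   5 86  5 ]
>Nanog synthetic_nanog_like
A [  6 83 83  4  5  6 84 ]
C [  5  5  5 86  4  5  6 ]
G [  4  6  6  5 87  5  5 ]
T [ 85  6  6  5  4 84  5 ]
>PouSox synthetic_pou_sox_composite
A [  5 84  3  84  84  4  6 84  2  2  5 87 89 83  4 ]
C [ 86  5 90   5   5  5  5  6  3  4 85  4  3  6  4 ]
G [  4  6  3   6   5  5 84  5  4 90  5  5  4  6  4 ]
T [  5  5  4   5   6 86  5  5 91  4  5  4  4  5 88 ]
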