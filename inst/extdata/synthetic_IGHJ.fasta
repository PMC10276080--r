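>X00000|IGHJ4*01|Homo sapiens|synthetic
TTTGACTACTGGGGGCAAGGCACGTTAGTCACTGTATCATCA
>X00000|IGHJ5*01|Homo sapiens|synthetic
AACTGGTTTGATTCCTGGGGACAAGGAACCTTAGTGACAGTCTCTAGT
>X00000|IGHJ6*01|Homo sapiens|synthetic
TATTATTACATGGATGTCTGGGGAAAAGGAACCACAGTGACTGTTTCAAGC
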