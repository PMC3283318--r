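>g01|t1
AUGAUG
>g02|t1
AUGAAAUAA
>g03|t1
ACGUACGUACGU
>g04|t1
AUGGCUAAGCUAGGCUGACGUG
>g05|t1
CCAUGGCCUAACCUAGGCUGACC
>g06|t1
GGCCGGCCGGCC
>g07|t1
AUGAUGAUGA
>g08|t1
ACGUNACGU
>g09|t1
AC
>g10|t1
atggctaagctaggctgacgtg
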