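>neu net-neutral ELK 18-mer
EKLKELLEKLLEKLKELL
>hyd hydrophobic ELK 18-mer
EKLLELLKKLLELLKELL
>pos net-positive ELK 18-mer
EKLKALLEKLKAKLKELL
>neg net-negative ELK 18-mer
EELKEKLEELKEKLEEKL
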