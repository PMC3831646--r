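>Deino-f-326-350
CGGGAGGCAGCAGTTAGGAATCTTC
>Deino-r-758-785
GTTTAGGGYGTGGACTACCCGGGTATCT
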