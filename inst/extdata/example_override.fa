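>R17 synthetic placeholder override
ELAEKSALQEQFLPSAE
>R12 synthetic placeholder override
EAVAEELAKSQA
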