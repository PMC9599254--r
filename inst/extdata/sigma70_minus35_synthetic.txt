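TTGACA
TTGACA
TTGACT
TTGATA
TTTACA
TTGCCA
TGGACA
CTGACA
TTGACG
TTCACA
TTGAAA
TTGTCA
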