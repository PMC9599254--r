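TATAAT
TATAAT
TATACT
TAAAAT
TACAAT
TATGAT
CATAAT
TATATT
GATAAT
TATCAT
TTTAAT
TAGAAT
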