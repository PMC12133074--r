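phrase,kind
zwanger,signal
zwangerschap,signal
graviditeit,signal
weken amenorroe,signal
niet zwanger,decoy
zwangerschapstest negatief,decoy
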