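>ctd_synthetic synthetic 30-residue stand-in for a C-terminal domain window (688-717 numbering); 2 prolines, not the biological sequence
MKELARSQVPNDLTGYIEAKWPHSDNRFQL
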