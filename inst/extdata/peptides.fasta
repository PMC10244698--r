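>RRM1_rBH3 start=102 FITC-labelled PTBP1 rBH3 peptide (residues 102-124)
NTEEAANTMVNYYTSVTPVLRGQ
>BAK_BH3 FITC-labelled BAK BH3 peptide
GQVGRQLAIIGDDINRRYD
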