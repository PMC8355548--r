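# Synthetic example marker list matching the make_counts() generator
# defaults. Replace with literature-derived deuterosomal-cell markers
# for real data (one gene id per line).
DeutM01
DeutM02
DeutM03
DeutM04
DeutM05
DeutM06
DeutM07
DeutM08
DeutM09
DeutM10
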