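# Synthetic example marker list matching the make_counts() generator
# defaults. Replace with literature-derived mature-MCC markers for real
# data (one gene id per line).
MatM01
MatM02
MatM03
MatM04
MatM05
MatM06
MatM07
MatM08
MatM09
MatM10
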