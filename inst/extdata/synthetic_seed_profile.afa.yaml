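# Synthetic seed DDE-domain profile (generated, not a database alignment).
# 1-based columns of the catalytic D, D, D/E residues:
catalytic_cols: [121, 192, 227]
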