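# Example construct specification: expanded exon-1-like chain.
# `fasta` optionally overrides the placeholder N17/R17/R12 sequences.
n: 74
label: HTT-74Q
fasta: example_override.fa
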