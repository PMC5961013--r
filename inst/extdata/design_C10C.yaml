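# Cysteine-constrained 10-mer NNK library (CX10C display format)
name: C10C
n_random_codons: 10
constrained: yes
cys_codon: TGT
upstream_flank: ACGTCCAACGTGGC
downstream_flank: GGCCCCAGAGGC
barcode: ACGTC
barcode_offset: 0
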