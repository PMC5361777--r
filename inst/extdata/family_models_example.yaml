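# Example family-model configuration. Each family may declare diagnostic
# motifs (regular expressions over the amino-acid alphabet), the minimum
# number of distinct motifs required for a motif-based call, and an optional
# reference FASTA (path relative to this file) for identity-based calls.
# Families listed without motifs are identity-only.
I2:
  name: Kunitz
  motifs: [GPCKAR, FYGGCG]
  min_motif_hits: 2
I25:
  name: cystatin
  motifs: [QVVAGW, NYFIKV]
  min_motif_hits: 2
I72:
  name: chimadanin
  motifs: []
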