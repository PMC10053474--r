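# Default protocode configuration: codon assignments of the four protocodes
# over their two-base alphabets, placeholder amino acids (X1, X1*, X2) with a
# deleted flag, and codon-level complement pairs (aa, codon, aa, codon) whose
# codons are reverse complements within the protocode.
#
# Constraints encoded here: dominant and recessive protocodes of one base
# family compete for the same eight two-base codons; every codon is assigned
# exactly once within a protocode; fusion of this table reproduces the
# standard genetic code (checked by validateAgainstSgc()).
AU-dominant:
  bases: [A, U]
  dominance: dominant
  members:
    "K": [AAA]
    "F": [UUU]
    "N": [AAU]
    "I": [AUU, AUA]
    "Y": [UAU]
    X1: [UAA]
    "X1*": [UUA]
  deleted: ["X1", "X1*"]
  complement_pairs:
    - ["K", AAA, "F", UUU]
    - ["N", AAU, "I", AUU]
    - ["Y", UAU, "I", AUA]
    - ["X1", UAA, "X1*", UUA]
AU-recessive:
  bases: [A, U]
  dominance: recessive
  members:
    "E": [AAA]
    "L": [UUU, UUA]
    "D": [AAU]
    "V": [AUU, AUA]
    "Q": [UAA]
    "H": [UAU]
  deleted: []
  complement_pairs:
    - ["E", AAA, "L", UUU]
    - ["D", AAU, "V", AUU]
    - ["H", UAU, "V", AUA]
    - ["Q", UAA, "L", UUA]
GC-dominant:
  bases: [G, C]
  dominance: dominant
  members:
    "G": [GGG, GGC]
    "P": [CCC, CCG]
    "A": [GCC, GCG]
    "R": [CGC, CGG]
  deleted: []
  complement_pairs:
    - ["G", GGG, "P", CCC]
    - ["G", GGC, "A", GCC]
    - ["A", GCG, "R", CGC]
    - ["P", CCG, "R", CGG]
GC-recessive:
  bases: [G, C]
  dominance: recessive
  members:
    "S": [CCC, CCG, GGC]
    "T": [GCC, GCG]
    "C": [CGC]
    "R": [GGG]
    X2: [CGG]
  deleted: ["X2"]
  complement_pairs:
    - ["R", GGG, "S", CCC]
    - ["S", GGC, "T", GCC]
    - ["T", GCG, "C", CGC]
    - ["S", CCG, "X2", CGG]
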