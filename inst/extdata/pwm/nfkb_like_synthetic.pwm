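>NFKB_LIKE_SYNTH synthetic NF-kB-like (REL-family) count matrix
# SYNTHETIC matrix: counts constructed from the canonical kB-site consensus
# GGGRNNYYCC (100 observations per position). Not a TRANSFAC or JASPAR
# matrix; shipped as a working default for Match-style scanning. Replace
# with a curated matrix for biological interpretation of hit positions.
A [  5  3  3 45 25 25  5  5  5  5 ]
C [  5  3  3  5 25 25 45 45 85 85 ]
G [ 85 91 91 45 25 25  5  5  5  5 ]
T [  5  3  3  5 25 25 45 45  5  5 ]
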