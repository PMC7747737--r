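# Synthetic template annotation (versioned curated input, v1).
# Template: template_mip_synthetic.fasta (MIPTMPL01), a synthetic PIP-like
# 280-aa scaffold carrying the canonical plasma-membrane-aquaporin residue
# signature: dual NPA motifs at the loop-B/loop-E re-entrant helices, the
# aromatic/arginine (ar/R) selectivity filter F-H-T-R (helix 2, helix 5,
# loop-E LE1/LE2) and Froger positions P1-P5 = Q-S-A-F-W (loop C, loop E,
# helix 6), the residue layout described for PIP1-type aquaporins
# (Froger et al. 1998 Protein Sci 7:1458; Torneroth-Horsefield et al. 2006
# Nature 439:688 for the SoPIP1;2 fold). Coordinates are 1-based on the
# template sequence.
name	position
npa_lb	100
npa_le	219
H2	80
H5	195
LE1	224
LE2	225
P1	150
P2	227
P3	228
P4	250
P5	251
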