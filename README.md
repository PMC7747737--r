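# aquamip

Genome-wide characterization of plant aquaporin (MIP) families in R.

Plant aquaporins — the major intrinsic protein (MIP) superfamily, split into
the PIP, TIP, NIP, SIP and XIP subfamilies — are channel proteins whose
substrate selectivity is written into a handful of residues: the two
Asn-Pro-Ala (NPA) motifs on the loop-B/loop-E re-entrant helices, the
aromatic/arginine (ar/R) selectivity filter (one residue each on helices 2
and 5, two on loop E), and Froger's positions P1–P5. A genome-wide census of
a family therefore runs through a fixed sequence of desk analyses: curate
candidate sequences, classify subfamilies, read off the selectivity
residues, predict transported substrates from the literature, build a
distance phylogeny, design and QC qPCR primers, and quantify relative
expression. `aquamip` implements that whole pipeline as reusable, tested
functions, with deterministic synthetic-data generators so every stage can
be validated without downloads.

For whom: plant molecular biologists running an aquaporin (or other gene
family) census, and bioinformaticians who want the individual pieces —
template-anchored residue transfer, neighbour joining with pinned
conventions, nearest-neighbour primer thermodynamics, geNorm/2^-ΔΔCt — as
auditable building blocks.

## The core methods, briefly

* **Curation** — a candidate is kept only if it carries two loop motifs from
  the degenerate alphabet `[NS]-P-[AVSTLI]` in distinct halves of the
  sequence (the closure of the observed variants NPA, NPS, NPV, NPT, NPL,
  SPI, SPA); shorter sequences aligning to a retained record at ≥ 98%
  identity over their full length are removed as redundant partials.
* **Residue transfer** — global alignment (BLOSUM62, gap open 10, extend
  0.5) of each protein to an annotated template maps every named site
  (NPA starts, ar/R = H2/H5/LE1/LE2, Froger P1–P5) to a query coordinate;
  an independent motif scan cross-checks the NPA sites within ±5 residues.
* **Phylogeny** — p-distances with pairwise deletion, Poisson correction
  `d = −ln(1 − p)`, Saitou–Nei neighbour joining with a deterministic
  tie-break, and column-bootstrap support.
* **Transport prediction** — a rule base (data, not code) mapping residue
  constraints to substrate sets `{CO2, H2O2, NH3, urea, B, Si, As, Sb,
  Gly}` with per-rule evidence codes; the shipped default reproduces the
  published prediction column of the melon census verbatim.
* **Primer QC** — unified nearest-neighbour ΔH/ΔS sums for duplex, dimer
  and hairpin free energies (ungapped dimer model with an exact brute-force
  oracle), Tm, and the ΔG > −6.5 kcal/mol dimer acceptance screen.
* **Expression** — technical-replicate collapse, geNorm stability
  `M_j = mean_k sd_s log2(Q_j/Q_k)`, dilution-curve efficiency
  `E = 10^(−1/slope) − 1`, `2^-ΔΔCt` quantification, max-100 rescaling into
  the three tiers (10–100, 1–10, 0–1 ru), and qPCR-vs-RNA-seq concordance
  classes.

## Worked example

```r
library(aquamip)

feats <- load_feature_table(aquamip_extdata("table2_features.tsv"))
#> loaded 31 records; subfamily counts: PIP=12 TIP=8 NIP=8 SIP=2 XIP=1
s <- summarize_family(feats)
s$chromosome_counts[c("chr09", "chr04", "chr05")]
#> chr09 chr04 chr05
#>     6     5     5

res <- load_residue_table(aquamip_extdata("table3_residues.tsv"))
pred <- predict_all(res, load_rulebase())
pred[["CmNIP2;1"]]$substrates
#> [1] "Si"   "H2O2" "As"   "Sb"   "urea" "B"    "Gly"
nrow(diff_against_reference(pred, res)$diff)
#> [1] 0        # the rule base reproduces the published column exactly

pt <- load_primer_table(aquamip_extdata("table1_primers.tsv"))
duplex_dg(pt$forward[pt$gene_name == "CmPIP1;1"], params = "breslauer1986")
#> [1] -37.25763   # published panel prints -37.26 for this primer
```

The interpretation: the census holds 31 aquaporin genes (12 PIP, 8 TIP, 8
NIP, 2 SIP, 1 XIP) spread over 11 chromosomes with chromosome 9 densest;
the wide-pore NIP2-class signature (G-S-G-R filter) licenses silicon and
metalloid transport; and the full-primer free-energy column of the
published primer panel is reproduced by the older nearest-neighbour
parameter set that the classic screening web tools use.

The numbered scripts under `analysis/` run the same steps as narrative
drivers (census overview, signatures and transport, phylogeny, primer QC,
expression) and write their tables under `results/`.

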