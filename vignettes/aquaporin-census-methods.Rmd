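---
title: "Methods: how aquamip runs an aquaporin census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how aquamip runs an aquaporin census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aquamip` packages the desk side of a genome-wide plant aquaporin (MIP)
census. This vignette is the package's account of the science: the models
each stage assumes, the tunable parameters and their defaults, the
numerical conventions, what the synthetic generators do and do not emulate,
and the design choices that were genuinely open.

## Candidate curation

A functional MIP monomer carries two re-entrant loops (B and E) whose tips
meet at the pore centre as a pair of NPA-type motifs. Curation therefore
keeps a candidate only if `scan_npa()` finds loop motifs in *both halves*
of the sequence. The motif alphabet is the degenerate closure
`[NS]-P-[AVSTLI]` of all variants observed across the plant subfamilies
(NPA, NPS, NPV, NPT, NPL and the X-intrinsic SPI/SPA); widening it further
is a deliberate configuration change, not a default, because a looser
alphabet starts matching background tripeptides.

Redundant records — truncated database entries, or the upstream fragments a
raw homology harvest drags in — are removed when they align over their full
length to a longer retained record at ≥ `identity_threshold` (default
0.98, the identity level at which such fragments are indistinguishable from
partial copies). Records that fail the dual-motif test while sharing a gene
name with a retained record are tagged `transcript_variant` rather than
`missing_npa`, which keeps the two failure modes distinguishable in the
report.

## Template-anchored residue transfer

The selectivity-determining residues are read off by positional transfer: a
Needleman–Wunsch global alignment (BLOSUM62, affine gap open 10, extension
0.5 — the classic protein-homology setting at the ~20–40% identity range
where MIP subfamilies sit) maps every annotated template site to a query
coordinate, and the query letters at those coordinates form the signature
(two NPA motifs, ar/R filter H2/H5/LE1/LE2, Froger P1–P5). Alignment near
re-entrant loops can jitter by a residue or two, so the NPA sites are
cross-checked against the independent motif scan: if the aligned 3-mer is
not a loop motif but a scanned motif lies within ±5 residues of the mapped
site, the scanned motif wins and the event is logged in the signature's
`notes`. A signature with more than two unaligned named sites is flagged
low-confidence rather than rejected.

The packaged template (`template_mip_synthetic.fasta`) is a synthetic
280-residue PIP-like scaffold carrying the canonical plasma-membrane
signature (NPA/NPA, F-H-T-R, Q-S-A-F-W) at annotated coordinates; the
annotation file documents its provenance. The machinery is agnostic to the
template: a curated annotation of a real reference protein can be supplied
through `load_template()` and everything downstream follows it.

## Subfamily classification

`classify_subfamily()` scores a query against a labelled panel by
global-alignment percent identity and calls the best scorer's subfamily,
with ties broken to the earlier panel member and calls below 0.35
similarity returned as `unclassified` (that floor sits below
random-homology expectation for MIPs, so it only fires on non-MIP input).
Because no curated real panel ships with the package, tests and drivers
build panels from the family generator's subfamily founders; with a real
panel the function behaves identically.

## Physico-chemical properties

The isoelectric point solves `net_charge(pH) = 0` by bisection on
`[0, 14]` to a residual `|charge| < 1e-4`, using the Bjellqvist pKa set
(side chains C 9.0, D 4.05, E 4.45, H 5.98, K 10.0, R 12.0, Y 10.0;
first-residue-dependent N-terminal values; C-terminal 3.55 with D/E
exceptions) — the set behind the common web calculators, so values are
comparable with published tables. The charge function is strictly
decreasing (the termini are always ionizable), so the root is unique; the
test suite checks the bisection against a 0.001-step grid scan to within
0.005 pH units. Molecular mass is the sum of IUPAC average residue masses
plus one water, reported in kDa at full precision and rounded only for
display. `X` residues are a hard error by default; `allow_x = TRUE`
substitutes the mean residue mass and no ionizable contribution.

## Phylogeny

Distances are observed proportions of differing sites under *pairwise
deletion* (a column is excluded only for the pair in which it carries a gap
or X), Poisson-corrected as `d = −ln(1 − p)` to account for multiple
substitutions. Sequences enter as a template-anchored star alignment
(columns = template positions; insertions relative to the template are
dropped), a desk-scale substitute for a full multiple alignment;
externally produced MSAs can be passed directly to `distance_matrix()`.

Neighbour joining follows Saitou–Nei with three pinned conventions, chosen
because the method itself does not dictate them: (1) ties on the Q
criterion break to the lexicographically lowest label pair, an internal
node inheriting the smallest label among its leaves, so the tree is a pure
function of the matrix; (2) negative branch-length estimates are clamped to
zero and listed in an attribute (the convention of the mainstream tree
software); (3) saturated or incomparable pairs are imputed to 1.25 × the
largest finite distance with a warning. NJ is exact on additive matrices —
the property suite verifies bipartition *and* path-length recovery on
random 6–10-leaf trees, and cross-checks topologies against the independent
`ape::nj` on noisy matrices.

Bootstrap support resamples alignment columns with replacement; replicate
`r` seeds its RNG at `seed + r`, so supports are reproducible and
independent of execution order. Support is the percentage of replicates
containing each internal bipartition of the point tree, attached as node
labels for Newick export.

## Transport prediction as data

The substrate predictions of a census are literature synthesis, so the
engine is generic and the science lives in a rule file: each rule carries a
subfamily pattern (prefix-matched), residue constraints over
`{LB, LE, H2, H5, LE1, LE2, P1–P5}` (bracket sets allowed), a substrate
set, per-substrate evidence codes and a literature tag. A prediction is the
union of all firing rules; no firing rule means `unpredicted`, mirroring
the dashes in published prediction columns. Water is emitted with code
`default` for every classified subfamily and excluded from regression
diffs, since published columns never list it. Evidence codes are stored per
rule, not per gene — published tables occasionally print different code
strings for genes with identical signatures, which a signature-keyed rule
base cannot (and should not) reproduce; the regression surface is the
substrate set. The shipped default rule base reproduces the packaged
31-gene prediction column with zero diff, and an ablation test confirms
that deleting a rule surfaces exactly the genes that depended on it.

## Primer thermodynamics

Free energies are nearest-neighbour ΔH/ΔS sums. Two parameter sets ship:

* `santalucia1998` (default) — the unified table at its published 1 M NaCl
  baseline, evaluated at 37 °C with initiation and terminal-pair terms, the
  self-complementarity entropy correction, and an entropic salt correction
  (0.368 cal K⁻¹ per stack per ln M) when conditions deviate. Used for
  dimers, hairpins and Tm.
* `breslauer1986` — the older stack table evaluated at 25 °C without an
  initiation term. This is what the classic primer-screening web tools
  report as "total ΔG", and it reproduces the packaged primer panel's
  full-primer column: median absolute error 0.00 kcal/mol over 62 primers,
  59/62 within 1.5 (the three outliers are isolated single-strand
  discrepancies in the published panel itself).

The dimer model is deliberately *ungapped*: strands slide antiparallel,
and every maximal run of ≥ 2 complementary pairs is scored as a short
duplex (stacks + initiation; mismatched flanks ignored). That choice keeps
an exact brute-force oracle feasible — the suite checks the scorer against
full offset enumeration on 500 random oligos — at the cost of missing
bulged dimers that vendor tools with internal-loop models report; computed
dimer values are therefore systematically weaker than a gapped tool's for
sequences whose best structure is bulged. Hairpins enumerate stem-loop
decompositions with stem ≥ 3 bp and loop ≥ 3 nt, with a tabulated loop
penalty to length 10 and Jacobson–Stockmayer extrapolation beyond.

The acceptance screen passes a pair when every self-/hetero-dimer ΔG is
*less stable* than −6.5 kcal/mol (the census's stated rule), hairpins stay
above −3 kcal/mol, and length (15–30 nt) and GC (20–80%) fall in bounds;
all failure reasons are enumerated. Published amplicon melting temperatures
are not a comparison surface (amplicon sequences are not part of the primer
table); primer Tm uses the two-state formula at 50 mM monovalent / 0.25 µM
oligo by default.

## Expression analysis

Technical triplicates collapse by mean after dropping any replicate more
than 0.5 cycles from the cell median (provided two survive) — an explicit
convention, logged per event, standing in for the unspecified outlier
handling of typical qPCR workflows. geNorm stability is implemented from
its defining statistic, `M_j = mean_{k≠j} sd_s log2(Q_j/Q_k)` with
`Q = (1+E)^(Ct_min − Ct)`, including the stepwise-exclusion trace;
efficiencies default to 1 (perfect doubling) when unmeasured. Dilution
curves give `E = 10^(−1/slope) − 1` from the least-squares slope of Ct
against log10 concentration, flagged outside 80–120%.

`ddct()` has two modes because two questions are asked of the same data.
For tissue contrasts, the calibrator is the per-gene mean ΔCt of the root
samples (the natural baseline tissue when one must be chosen), giving
`2^-ΔΔCt` fold changes with the calibrator tissue at exactly 1. For
cross-gene profiling, `calibrator = NULL` returns reference-normalized
quantities `2^-ΔCt`, the only scale on which different genes can be ranked
and rescaled to relative units. Rescaling anchors the dataset maximum at
100 ru; tier boundaries (10, 100], (1, 10], [0, 1] are half-open with the
boundary in the lower tier so the tiers partition; undetected entries carry
0 ru. Tissue comparisons use Welch's t (unequal variance — the realistic
assumption at n = 3–6), and the platform-comparison groups use one-way
ANOVA with Tukey HSD.

Cross-platform concordance rescales each platform to its own max = 100 and
classifies each gene by per-tissue fold difference (default threshold
3-fold, values floored at 0.5 ru before ratioing to keep near-zero entries
from producing unstable folds): concordant in all tissues, in some
(`tissue_specific`), or in none (`discordant`).

## Synthetic data: what it does and does not emulate

The generators make every stage testable offline and are first-class,
tested code. `generate_family()` derives one founder per subfamily from the
annotated template (signature planted, then founder-level divergence at
0.25 substitutions/site outside the annotated sites) and members from
founders (default 0.05 background, optional short indels that avoid a ±2
window around annotated sites, so recovery failures isolate alignment
errors). `generate_census_input()` reproduces the *shape* of a raw
homology harvest: 31 true genes (12/8/8/2/1 across subfamilies) plus
NPA-less transcript variants, an exact partial duplicate and upstream
fragments carrying only the loop-E motif — 37 candidates of which
curation must retain exactly 31. `generate_ct()` draws
`Ct = Ct₀ − log_{1+E}(abundance) + N(0, σ)` with technical triplicates,
biological log2 jitter and a detection ceiling (default 38 cycles);
`generate_platform_pair()` builds concordance classes by construction, with
two dominant concordant anchors so each platform's rescaling maximum falls
on a different gene and the classes still survive rescaling.

What passing these tests shows: the pipeline's operations recover planted
truth under controlled substitution, indel, and noise processes. What it
does not show: real proteomes have subfamily-specific composition,
insertions and terminal extensions far from i.i.d. substitution models, and
real Ct data carry plate, dilution and pipetting structure the generator
does not model. Results on real data therefore inherit the alignment and
noise assumptions above, not the generator's guarantees.

## Problem sizes and numerical conventions

The test and acceptance runs use: 200 sequences for planted-signature
recovery, 500 random oligo pairs for the dimer oracle, 100 random 50-mers
for the pI grid scan, 20 random 6–10-leaf trees for NJ recovery, 200
bootstrap replicates for the synthetic census, and 50 simulation seeds for
fold-change recovery — sizes at which each property is measured with
comfortable margins while the whole suite stays interactive. Bisection
stops at |charge| < 1e-4; distances are exact rationals of site counts
before correction; all seeds are explicit arguments and every generator is
a pure function of (spec, seed).

## Known limitations

* The dimer/hairpin models are ungapped/two-state; vendor tools with
  internal-loop thermodynamics will report stronger structures for bulged
  duplexes.
* The star alignment discards insertions relative to the template, which
  slightly compresses distances for sequences with long template-absent
  segments; supply a full MSA where that matters.
* The shipped template and classification panels are synthetic scaffolds:
  correct by construction for the machinery, but not substitutes for a
  curated reference annotation when analysing real proteins.
* Published subfamily mean pI/Mw values in census papers are often
  internally inconsistent with their own per-gene tables (rounding at
  different stages); `summarize_family()` recomputes from full precision
  and makes no attempt to match such printed means.
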