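#!/usr/bin/env Rscript
# Phylogeny of a synthetic census: star-align a generated 31-member family
# to the annotated template, build the Poisson-corrected NJ tree with
# bootstrap supports, and check subfamily monophyly.
suppressPackageStartupMessages(library(aquamip))
dir.create("results", showWarnings = FALSE)

tm <- load_template()
fam <- generate_family(c(rep("PIP1", 2), rep("PIP2", 10), rep("TIP", 8),
                         rep("NIP", 8), rep("SIP", 2), "XIP"),
                       tm, mutation_rate = 0.05, seed = 11)
aln <- star_align(setNames(fam$records$sequence, fam$records$record_id), tm)
tree <- bootstrap_support(aln, n_reps = 200, seed = 17)

sup <- attr(tree, "support")
anchor <- sort(rownames(aln))[1]
for (sf in c("PIP", "TIP", "NIP", "SIP")) {
  tips <- fam$records$record_id[startsWith(fam$records$subfamily, sf)]
  side <- if (anchor %in% tips) setdiff(sort(rownames(aln)), tips) else sort(tips)
  key <- paste(side, collapse = "|")
  cat(sprintf("%s clade monophyletic: %s (bootstrap %s%%)\n", sf,
              is_split(tree, tips),
              if (key %in% names(sup)) sup[[key]] else "-"))
}
cat(sprintf("median support over all %d internal edges: %.0f%% (shallow\n",
            length(sup), median(sup)))
cat("within-subfamily edges are weakly supported at this divergence, as\n")
cat("expected; the deep subfamily splits carry the signal)\n")

ape::write.tree(tree, "results/census_tree.nwk")
D <- distance_matrix(aln)
write.table(round(D, 4), "results/census_distances.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
cat("wrote results/census_tree.nwk (supports as node labels) and census_distances.tsv\n")
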