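# shared fixtures: the packaged template, the census subfamily layout, and
# an expression profile shaped like the study's three published tiers

the_template <- local({
  tm <- NULL
  function() {
    if (is.null(tm)) tm <<- load_template()
    tm
  }
})

census_subfamilies <- function() {
  c(rep("PIP1", 2), rep("PIP2", 10), rep("TIP", 8), rep("NIP", 8),
    rep("SIP", 2), "XIP")
}

# abundance table with 3 / 9 / 19 genes in the high/mid/low tiers, the
# dominant tonoplast isoform anchoring 100, one gene root-only and one
# below detection everywhere (the structure reported for the melon census)
fig4_abundance <- function() {
  res <- load_residue_table(aquamip_extdata("table3_residues.tsv"))
  genes <- res$gene_name
  g1 <- c("CmTIP1;1", "CmPIP1;1", "CmPIP1;2")
  g2 <- c("CmPIP2;2", "CmPIP2;3", "CmPIP2;6", "CmPIP2;10", "CmTIP3;1",
          "CmNIP2;1", "CmNIP2;2", "CmNIP5;1", "CmNIP5;2")
  g3 <- setdiff(genes, c(g1, g2))
  ab_of <- function(g) {
    if (g == "CmTIP1;1") 100
    else if (g %in% g1) c(40, 20)[match(g, setdiff(g1, "CmTIP1;1"))]
    else if (g %in% g2) 2 + 4 * match(g, g2) / length(g2)
    else 0.05 + 0.4 * match(g, g3) / length(g3)
  }
  ab <- do.call(rbind, lapply(genes, function(g) data.frame(
    gene = g, tissue = c("root", "leaf"),
    abundance = c(ab_of(g), ab_of(g) * 0.8), stringsAsFactors = FALSE)))
  ab$abundance[ab$gene == "CmXIP1;1"] <- 1e-6                      # undetectable
  ab$abundance[ab$gene == "CmPIP2;9" & ab$tissue == "leaf"] <- 1e-6 # root-only
  list(abundance = ab, tiers = list(group1 = g1, group2 = g2, group3 = g3))
}

random_protein <- function(n) paste(sample(aquamip:::AA20, n, replace = TRUE),
                                    collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
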