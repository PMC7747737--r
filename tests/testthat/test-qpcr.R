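make_ct <- function(gene, tissue, bio, tech, ct) {
  data.frame(gene = gene, sample = paste0(tissue, "_b", bio), tissue = tissue,
             bio_rep = bio, tech_rep = tech, ct = ct, stringsAsFactors = FALSE)
}

test_that("technical replicates collapse with the outlier rule", {
  ct <- rbind(make_ct("g", "root", 1, 1:3, c(20.0, 20.1, 20.2)),
              make_ct("g", "root", 2, 1:3, c(20.0, 20.1, 23.0)),
              make_ct("g", "root", 3, 1:3, rep(NA_real_, 3)))
  cc <- collapse_technical(ct)
  expect_equal(cc$ct[cc$sample == "root_b1"], 20.1)
  expect_equal(cc$ct[cc$sample == "root_b2"], 20.05)  # outlier dropped
  expect_true(is.na(cc$ct[cc$sample == "root_b3"]))   # all-missing: undetected
  expect_equal(nrow(attr(cc, "outliers")), 1L)
  expect_equal(attr(cc, "outliers")$ct, 23.0)
  expect_error(collapse_technical(transform(ct, ct = ct * 10)), "45")
})

test_that("geNorm M is zero iff pairwise log-ratios are sample-constant", {
  ct <- matrix(c(20, 21, 22, 23, 22, 23, 24, 25), 2, 4, byrow = TRUE,
               dimnames = list(c("A", "B"), paste0("s", 1:4)))
  g <- genorm_m(ct, c("A", "B"))
  expect_equal(unname(g$m), c(0, 0))
  ct2 <- ct; ct2["B", 1] <- 21
  g2 <- genorm_m(ct2, c("A", "B"))
  expect_true(all(g2$m > 0))
  # sample permutation leaves every M unchanged
  g3 <- genorm_m(ct2[, c(3, 1, 4, 2)], c("A", "B"))
  expect_equal(g3$m, g2$m)
})

test_that("a destabilized candidate ranks last almost always", {
  last <- 0L
  for (s in 1:100) {
    set.seed(s)
    m <- matrix(rnorm(5 * 8, 20, 0.1), 5, 8,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
    m["g5", ] <- m["g5", ] + rnorm(8, 0, 1)
    r <- genorm_m(m, paste0("g", 1:5))
    last <- last + (tail(r$ranking, 1) == "g5")
  }
  expect_gte(last, 96L)
  # the most stable candidate is selected; ties go to input order
  set.seed(1)
  m <- matrix(rnorm(3 * 6, 20, 0.05), 3, 6,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  r <- genorm_m(m, paste0("g", 1:3))
  expect_equal(r$selected, r$ranking[1])
  # undetected candidates are excluded with a warning
  m[1, 2] <- NA
  expect_warning(r2 <- genorm_m(m, paste0("g", 1:3)), "undetected")
  expect_equal(r2$excluded, "g1")
})

test_that("dilution-curve efficiency follows the closed form", {
  est <- efficiency_from_dilution(c(20, 23.3219, 26.6438), c(1, 0.1, 0.01))
  expect_equal(est$e_pct, 100, tolerance = 1e-2)
  x <- log10(c(1, 0.2, 0.04, 0.008))
  est2 <- efficiency_from_dilution(10 - 3.45 * x, c(1, 0.2, 0.04, 0.008))
  expect_equal(est2$e_pct, 94.9, tolerance = 0.05)
  expect_true(est2$in_range)
  est3 <- efficiency_from_dilution(10 - 3.10 * x, c(1, 0.2, 0.04, 0.008))
  expect_equal(est3$e_pct, 110.2, tolerance = 0.05)
  expect_error(efficiency_from_dilution(c(20, 21), c(1, 0.1)), "3 dilution")
  expect_error(efficiency_from_dilution(c(20, 21, 22), c(1, 1, 1)), "variance")
})

test_that("ddCt recovers simple constructed contrasts exactly", {
  # reference flat at 15; target one cycle lower in leaf than root
  ct <- rbind(make_ct("REF", "root", 1:2, 1, 15), make_ct("REF", "leaf", 1:2, 1, 15),
              make_ct("tgt", "root", 1:2, 1, 20), make_ct("tgt", "leaf", 1:2, 1, 19))
  dd <- ddct(ct, "REF", calibrator = "root")
  expect_equal(dd$rq[dd$tissue == "root"], 1)   # calibrator against itself
  expect_equal(dd$rq[dd$tissue == "leaf"], 2)
  # undetected tissue flagged, not fabricated
  ct2 <- rbind(ct, make_ct("g2", "root", 1:2, 1, 21),
               make_ct("g2", "leaf", 1:2, 1, NA_real_))
  dd2 <- ddct(ct2, "REF", calibrator = "root")
  expect_false(dd2$detected[dd2$gene == "g2" & dd2$tissue == "leaf"])
  expect_true(is.na(dd2$rq[dd2$gene == "g2" & dd2$tissue == "leaf"]))
  expect_error(ddct(transform(ct, ct = ifelse(gene == "REF", NA, ct)), "REF"),
               "reference gene undetected")
})

test_that("planted fold-changes are recovered within 10% on average", {
  ab <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 2),
                   tissue = rep(c("root", "leaf"), 3),
                   abundance = c(1, 2, 1, 8, 1, 0.5))
  err <- c()
  for (s in 1:50) {
    sim <- generate_ct(ab, ref_genes = "REF1", noise_sd = 0.2, bio_sd = 0,
                       seed = s)
    cc <- collapse_technical(sim$ct)
    dd <- ddct(cc, "REF1", calibrator = "root")
    fc <- attr(sim$truth, "fold_change")
    leaf <- dd[dd$tissue == "leaf", ]
    got <- leaf$rq[match(fc$gene, leaf$gene)]
    err <- c(err, abs(got - fc$fold_change) / fc$fold_change)
  }
  expect_lt(mean(err), 0.10)
})

test_that("rescaling anchors the maximum at 100 and tiers partition", {
  q <- data.frame(gene = c("a", "b", "c", "d"), tissue = "root",
                  rq = c(100, 5, 0.3, NA),
                  detected = c(TRUE, TRUE, TRUE, FALSE))
  rt <- rescale_and_tier(q)
  expect_equal(max(rt$ru), 100)
  expect_equal(rt$tier, c("group1", "group2", "group3", "group3"))
  expect_equal(rt$ru[4], 0)
  # order isomorphism and boundary-in-lower-tier convention
  q2 <- data.frame(gene = letters[1:4], tissue = "root",
                   rq = c(50, 5, 0.5, 0.05), detected = TRUE)
  rt2 <- rescale_and_tier(q2)
  expect_equal(order(rt2$ru), order(q2$rq))
  expect_equal(rt2$tier, c("group1", "group2", "group3", "group3"))
  expect_equal(rt2$ru[2], 10)  # exactly on the boundary -> lower tier
})

test_that("a tier profile shaped like the published census gives 3/9/19", {
  prof <- fig4_abundance()
  sim <- generate_ct(prof$abundance, ref_genes = "CmRAN", noise_sd = 0.2,
                     seed = 4)
  cc <- collapse_technical(sim$ct)
  dd <- ddct(cc, "CmRAN", calibrator = NULL)
  rt <- rescale_and_tier(dd)
  tiers <- attr(rt, "gene_tiers")
  expect_equal(unname(table(tiers)[c("group1", "group2", "group3")]),
               c(3L, 9L, 19L), ignore_attr = TRUE)
  expect_setequal(names(tiers)[tiers == "group1"], prof$tiers$group1)
  expect_setequal(names(tiers)[tiers == "group2"], prof$tiers$group2)
  # the undetectable isoform is never detected; the root-only one is
  expect_false(any(dd$detected[dd$gene == "CmXIP1;1"]))
  expect_true(dd$detected[dd$gene == "CmPIP2;9" & dd$tissue == "root"])
  expect_false(dd$detected[dd$gene == "CmPIP2;9" & dd$tissue == "leaf"])
})

test_that("platform comparison classifies constructed profiles", {
  # identical profiles: all concordant
  q <- data.frame(gene = rep(letters[1:3], each = 2),
                  tissue = rep(c("root", "leaf"), 3),
                  value = c(100, 80, 10, 8, 3, 2))
  cp <- compare_platforms(q, q)
  expect_true(all(cp$classes$class == "concordant"))
  # equal in roots, 10x apart in leaves: tissue-specific (roots concordant)
  r <- q
  r$value[r$gene == "b" & r$tissue == "leaf"] <- 0.8
  cp2 <- compare_platforms(q, r)
  expect_equal(cp2$classes$class[cp2$classes$gene == "b"], "tissue_specific")
  expect_equal(cp2$classes$concordant_tissues[cp2$classes$gene == "b"], "root")
  # generator truth is recovered exactly, including differing anchors
  pp <- generate_platform_pair(6, 9, 13, seed = 2)
  cp3 <- compare_platforms(pp$qpcr, pp$rnaseq)
  tab <- merge(cp3$classes, pp$truth, by = "gene")
  expect_equal(tab$class.x, tab$class.y)
  expect_equal(unname(table(tab$class.x)[c("concordant", "tissue_specific",
                                           "discordant")]),
               c(6L, 9L, 13L), ignore_attr = TRUE)
})

test_that("group tests behave under null and strong-effect regimes", {
  expect_equal(group_test(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_true(group_test(c(1, 1, 1), c(1, 1, 1))$degenerate)
  sig <- 0L
  for (s in 1:200) {
    set.seed(s)
    sig <- sig + group_test(rnorm(6, 0, 1), rnorm(6, 5, 1))$significant
  }
  expect_gte(sig, 199L)
  # Tukey on three equal groups rarely flags any pair (type-I control)
  flagged <- 0L
  for (s in 1:100) {
    set.seed(s)
    r <- tukey_groups(rnorm(18), rep(c("a", "b", "c"), each = 6))
    flagged <- flagged + (length(r$significant_pairs) > 0)
  }
  expect_lte(flagged, 6L)
})
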