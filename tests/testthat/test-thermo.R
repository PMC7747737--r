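test_that("the AT/AT duplex equals the hand-summed table entry", {
  # one AT stack + initiation on two terminal A.T pairs
  expect_equal(duplex_dg("AT"), nn_dg37("AT") + 2 * init_dg37("A") -
                 310.15 * (-1.4) / 1000,  # AT is self-complementary
               tolerance = 1e-9)
  hand <- nn_dg37("GC") + nn_dg37("CA") + init_dg37("G") + init_dg37("A")
  expect_equal(duplex_dg("GCA"), hand, tolerance = 1e-9)
})

test_that("duplex free energy is symmetric and rejects mismatched input", {
  set.seed(2)
  for (k in 1:10) {
    a <- random_dna(sample(10:25, 1))
    expect_equal(duplex_dg(a, revcomp(a)), duplex_dg(revcomp(a), a),
                 tolerance = 1e-12)
  }
  expect_error(duplex_dg("ACGTT", "ACGTT"), "reverse complement")
  expect_error(duplex_dg("ACGU"), "non-ACGT")
})

test_that("the older parameter set reproduces the published full-primer column", {
  pt <- load_primer_table(aquamip_extdata("table1_primers.tsv"))
  pt <- pt[pt$gene_name != "CmRAN", ]
  # the study's lead isoform primer: printed -37.26
  f1 <- pt$forward[pt$gene_name == "CmPIP1;1"]
  expect_equal(duplex_dg(f1, params = "breslauer1986"), -37.26,
               tolerance = 0.05)
  errs <- c(
    vapply(seq_len(nrow(pt)), function(i)
      duplex_dg(pt$forward[i], params = "breslauer1986") - pt$dg_primer_f[i], 1.0),
    vapply(seq_len(nrow(pt)), function(i)
      duplex_dg(pt$reverse[i], params = "breslauer1986") - pt$dg_primer_r[i], 1.0))
  # printed column reproduced within its tolerance for >= 90% of primers
  expect_gte(mean(abs(errs) <= 1.5), 0.9)
  expect_lte(median(abs(errs)), 0.1)
})

test_that("dimer search matches the brute-force offset oracle on 500 oligos", {
  set.seed(77)
  for (k in 1:250) {
    a <- random_dna(sample(15:25, 1))
    b <- random_dna(sample(15:25, 1))
    expect_equal(best_dimer_dg(a, b), oracle_dimer(a, b), tolerance = 1e-9)
    expect_equal(best_dimer_dg(a, a), oracle_dimer(a, a), tolerance = 1e-9)
  }
})

test_that("dimer search is symmetric and attains the full duplex optimum", {
  set.seed(12)
  for (k in 1:25) {
    a <- random_dna(sample(15:22, 1))
    b <- random_dna(sample(15:22, 1))
    expect_equal(best_dimer_dg(a, b), best_dimer_dg(b, a), tolerance = 1e-12)
    expect_equal(best_dimer_dg(a, revcomp(a)), duplex_dg(a),
                 tolerance = 1e-9)
  }
  expect_true(is.na(best_dimer_dg("AAAAAAAA")))
  # self-complementary restriction-site hexamer dimerizes on itself at offset 0
  expect_equal(best_dimer_dg("GAATTC", "GAATTC"), duplex_dg("GAATTC"),
               tolerance = 1e-9)
})

test_that("hairpins require a foldable stem and depend on orientation", {
  expect_true(is.na(hairpin_dg("AAAAAAAA")))
  hp <- hairpin_dg("GGGGAAAACCCC")
  # stem GGGG/CCCC (3 GG stacks) + 4-nt loop penalty
  expect_equal(hp, 3 * nn_dg37("GG") + 3.5, tolerance = 1e-9)
  s <- "GGGCGTTTTACGCAA"
  r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_false(isTRUE(all.equal(hairpin_dg(s), hairpin_dg(r))))
})

test_that("extending a strand never weakens its best dimer", {
  # every pairing available before extension is still available after it,
  # so the reported minimum can only decrease or stay
  set.seed(9)
  for (k in 1:20) {
    a <- random_dna(18)
    b <- random_dna(18)
    base <- best_dimer_dg(a, b)
    if (is.na(base)) next
    ext <- best_dimer_dg(paste0("A", a, "A"), b)
    expect_lte(ext, base + 1e-9)
  }
})

test_that("primer screening enumerates failure reasons", {
  set.seed(4)
  a <- "TGCACCCTTTGGACTTCTTC"
  b <- "GATGTAGTAGCCATCCCGTAAAC"
  rep_ <- screen_pair(a, b)
  expect_true(rep_$pass)
  expect_length(rep_$failed_checks, 0)
  # 3' ends engineered reverse-complementary -> strong hetero-dimer
  bad_r <- paste0(substr(b, 1, 15), revcomp(substr(a, 13, 21)))
  rep2 <- screen_pair(a, bad_r)
  expect_false(rep2$pass)
  expect_true(any(grepl("hetero-dimer", rep2$failed_checks)))
  # length bound
  rep3 <- screen_pair("ACGTACGTACGT", b)
  expect_true(any(grepl("length", rep3$failed_checks)))
})

test_that("the published primer set passes the dimer screen almost everywhere", {
  pt <- load_primer_table(aquamip_extdata("table1_primers.tsv"))
  pt <- pt[pt$gene_name != "CmRAN", ]
  pass <- vapply(seq_len(nrow(pt)), function(i)
    screen_pair(pt$forward[i], pt$reverse[i])$pass, TRUE)
  expect_gte(sum(pass), 29L)
})
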