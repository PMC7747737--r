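test_that("NPA scanning finds canonical and degenerate loop motifs", {
  hits <- scan_npa("AAANPAAAANPAAA")
  expect_equal(hits$position, c(4L, 10L))
  expect_equal(hits$motif, c("NPA", "NPA"))
  expect_true(all(hits$canonical))

  # degenerate variants seen across the subfamilies, incl. overlap tolerance
  hits2 <- scan_npa("GGNPSGGNPVGGSPIGGSPAGGNPTGGNPL")
  expect_equal(hits2$motif, c("NPS", "NPV", "SPI", "SPA", "NPT", "NPL"))
  expect_false(any(hits2$canonical))
  expect_equal(nrow(scan_npa("AAAA")), 0L)
})

test_that("template self-extraction is exact", {
  tm <- the_template()
  sig <- extract_signature(tm$sequence, tm)
  expect_equal(sig$npa_lb, "NPA")
  expect_equal(sig$npa_le, "NPA")
  expect_equal(unname(sig$arr), c("F", "H", "T", "R"))
  expect_equal(unname(sig$froger), c("Q", "S", "A", "F", "W"))
  expect_false(sig$low_confidence)
  expect_equal(unname(sig$coords), unname(c(
    tm$positions[c("npa_lb", "npa_le", "H2", "H5", "LE1", "LE2")],
    tm$positions[paste0("P", 1:5)])))
})

test_that("alignment maps survive substitutions and internal deletions", {
  tm <- the_template()
  s <- tm$sequence
  # single substitution: identity map, substitution visible at the site
  s2 <- s
  substr(s2, 140, 140) <- if (substr(s, 140, 140) == "W") "Y" else "W"
  map <- align_to_template(s2, s)
  expect_equal(map, seq_len(nchar(s)))
  # 3-residue internal deletion: deleted sites unaligned, others shifted
  s3 <- paste0(substr(s, 1, 129), substr(s, 133, nchar(s)))
  map3 <- align_to_template(s3, s)
  expect_true(all(is.na(map3[130:132])))
  expect_equal(map3[1:129], 1:129)
  expect_equal(map3[133:nchar(s)], (133:nchar(s)) - 3L)
})

test_that("signatures planted by the generator are recovered", {
  tm <- the_template()
  fam <- generate_family(c("PIP2", "TIP", "NIP", "SIP", "XIP"), tm,
                         mutation_rate = 0.05, seed = 21)
  for (i in seq_len(nrow(fam$records))) {
    sig <- extract_signature(fam$records$sequence[i], tm)
    truth <- fam$truth[fam$truth$record_id == fam$records$record_id[i], ]
    got <- c(aquamip:::chars(sig$npa_lb), aquamip:::chars(sig$npa_le),
             unname(sig$arr), unname(sig$froger))
    expect_equal(got, truth$residue, info = fam$records$record_id[i])
  }
})

test_that("an unusual planted filter (F-N-A-R, K at P1) is recovered exactly", {
  tm <- the_template()
  odd <- list(PIP2 = list(lb = "NPA", le = "NPA",
                          arr = c("F", "N", "A", "R"),
                          froger = c("K", "S", "A", "F", "W")))
  fam <- generate_family("PIP2", tm, mutation_rate = 0.05, planted = odd,
                         seed = 8)
  sig <- extract_signature(fam$records$sequence[1], tm)
  expect_equal(unname(sig$arr), c("F", "N", "A", "R"))
  expect_equal(unname(sig$froger)[1], "K")
})

test_that("curation discards fragments, duplicates and NPA-less variants", {
  tm <- the_template()
  ci <- generate_census_input(tm, seed = 7)
  expect_equal(nrow(ci$records), 37L)
  rep_ <- curate(ci$records[c("record_id", "sequence", "gene_name")])
  expect_setequal(rep_$retained, ci$expected_retained)
  expect_equal(length(rep_$retained), 31L)
  m <- merge(rep_$discarded, ci$expected_discarded, by = "record_id")
  expect_equal(nrow(m), 6L)
  expect_equal(m$reason.x, m$reason.y)
  # every input id appears exactly once across retained + discarded
  expect_setequal(c(rep_$retained, rep_$discarded$record_id),
                  ci$records$record_id)
  # an exact copy is discarded as a redundant duplicate
  two <- data.frame(record_id = c("a", "b"),
                    sequence = rep(ci$records$sequence[1], 2),
                    stringsAsFactors = FALSE)
  cr2 <- curate(two)
  expect_equal(cr2$retained, "a")
  expect_equal(cr2$discarded$reason, "partial_duplicate")
  expect_error(curate(two, identity_threshold = 0), "identity_threshold")
})

test_that("every retained record carries loop motifs in both halves", {
  tm <- the_template()
  ci <- generate_census_input(tm, seed = 19)
  rep_ <- curate(ci$records[c("record_id", "sequence", "gene_name")])
  for (id in rep_$retained) {
    s <- ci$records$sequence[ci$records$record_id == id]
    hits <- scan_npa(s)
    expect_true(any(hits$position <= nchar(s) / 2) &&
                  any(hits$position > nchar(s) / 2), info = id)
  }
})

test_that("subfamily classification calls panel members and their relatives", {
  tm <- the_template()
  fam <- generate_family(rep(c("PIP1", "PIP2", "TIP", "NIP", "SIP", "XIP"), 2),
                         tm, mutation_rate = 0.08, seed = 3)
  panel <- data.frame(record_id = names(fam$founders),
                      subfamily = sub("[0-9]$", "", names(fam$founders)),
                      sequence = unname(fam$founders), stringsAsFactors = FALSE)
  # a panel member classifies as itself with score 1
  self <- classify_subfamily(panel$sequence[3], panel)
  expect_equal(self$label, panel$subfamily[3])
  expect_equal(self$score, 1)
  expect_equal(self$best_reference, panel$record_id[3])
  # members classify into their generating subfamily
  for (i in seq_len(nrow(fam$records))) {
    call <- classify_subfamily(fam$records$sequence[i], panel)
    expect_equal(call$label, sub("[0-9]$", "", fam$records$subfamily[i]))
    expect_gte(call$score, call$margin)
    expect_gte(call$margin, 0)
  }
  expect_error(classify_subfamily(panel$sequence[1], panel[0, ]), "empty")
  # junk sequence falls below the similarity floor
  expect_equal(classify_subfamily(strrep("G", 60), panel)$label, "unclassified")
})

test_that("family summaries reproduce the published table statistics", {
  feats <- suppressMessages(load_feature_table(aquamip_extdata("table2_features.tsv")))
  s <- summarize_family(feats)
  expect_equal(as.integer(s$chromosome_counts[c("chr09", "chr04", "chr05")]),
               c(6L, 5L, 5L))
  expect_equal(unname(s$tmh_tally[["5"]]), 4L)
  pip <- s$subfamily_stats[s$subfamily_stats$subfamily == "PIP", ]
  expect_equal(pip$max_length, 292L)
  expect_equal(pip$n, 12L)
  res <- load_residue_table(aquamip_extdata("table3_residues.tsv"))
  pips <- res$gene_name[parse_gene_name(res$gene_name)$subfamily == "PIP"]
  expect_equal(count_residue_at(res, "p1", "Q", genes = pips), 9L)
})
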