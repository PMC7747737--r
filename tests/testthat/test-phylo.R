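test_that("p-distance uses pairwise deletion", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("A-AA", "ATAA"), 0)      # 0 mismatches over 3 sites
  expect_equal(p_distance("AXAA", "ATAA"), 0)      # X excluded like a gap
  sat <- p_distance("--", "AA")
  expect_true(is.na(sat) && isTRUE(attr(sat, "saturated")))
  expect_error(p_distance("AA", "AAA"), "length")
})

test_that("Poisson correction matches the closed form and dominates p", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), log(2), tolerance = 1e-12)
  expect_equal(poisson_correct(0.99), -log(0.01), tolerance = 1e-12)
  expect_true(is.infinite(poisson_correct(1)))
  expect_error(poisson_correct(-0.1), "\\[0, 1\\]")
  p <- seq(0, 0.95, by = 0.05)
  expect_true(all(poisson_correct(p) >= p))
  expect_true(all(poisson_correct(p[p > 0]) > p[p > 0]))
})

test_that("three taxa resolve by the closed three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["a"]], 1)  # (3+4-5)/2
  expect_equal(len[["b"]], 2)  # (3+5-4)/2
  expect_equal(len[["c"]], 3)  # (4+5-3)/2
})

test_that("a known four-taxon additive matrix is recovered exactly", {
  tr0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  D <- cophenetic(tr0)[LETTERS[1:4], LETTERS[1:4]]
  tr <- neighbor_joining(D)
  expect_setequal(tree_bipartitions(tr), tree_bipartitions(tr0))
  expect_equal(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-9)
})

test_that("NJ reproduces the bipartitions of random additive trees", {
  set.seed(42)
  for (k in 1:12) {
    n <- sample(6:10, 1)
    tr0 <- ape::unroot(ape::rtree(n, br = function(m) runif(m, 0.1, 1)))
    D <- cophenetic(tr0)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    tr <- neighbor_joining(D)
    expect_setequal(tree_bipartitions(tr), tree_bipartitions(tr0))
    expect_lt(max(abs(cophenetic(tr)[rownames(D), colnames(D)] - D)), 1e-6)
  }
})

test_that("NJ agrees with the ape reference implementation on noisy input", {
  set.seed(1)
  for (k in 1:5) {
    n <- 8
    M <- matrix(runif(n * n, 0.05, 1), n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    rownames(M) <- colnames(M) <- letters[1:n]
    expect_setequal(tree_bipartitions(neighbor_joining(M)),
                    tree_bipartitions(ape::nj(M)))
  }
  expect_error(neighbor_joining(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                                c("a", "b")))),
               "at least 3")
  bad <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("synthetic subfamilies are monophyletic in the census tree", {
  tm <- the_template()
  fam <- generate_family(census_subfamilies(), tm, mutation_rate = 0.05,
                         seed = 11)
  aln <- star_align(setNames(fam$records$sequence, fam$records$record_id), tm)
  tree <- neighbor_joining(distance_matrix(aln))
  for (sf in c("PIP", "TIP", "NIP", "SIP")) {
    tips <- fam$records$record_id[startsWith(fam$records$subfamily, sf)]
    expect_true(is_split(tree, tips), info = sf)
  }
  # Newick round-trip is stable
  nwk <- ape::write.tree(tree)
  expect_identical(ape::write.tree(ape::read.tree(text = nwk)), nwk)
})

test_that("bootstrap supports are reproducible, label-order invariant and calibrated", {
  tm <- the_template()
  fam <- generate_family(c(rep("PIP2", 4), rep("TIP", 4)), tm,
                         mutation_rate = 0.03, seed = 13)
  aln <- star_align(setNames(fam$records$sequence, fam$records$record_id), tm)
  b1 <- bootstrap_support(aln, 100, seed = 5)
  b2 <- bootstrap_support(aln, 100, seed = 5)
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  # permuting row order leaves every support unchanged
  perm <- sample(nrow(aln))
  b3 <- bootstrap_support(aln[perm, ], 100, seed = 5)
  shared <- intersect(names(attr(b1, "support")), names(attr(b3, "support")))
  expect_identical(attr(b1, "support")[shared], attr(b3, "support")[shared])
  # the deep split between the two planted subfamilies is near-certain
  pip_key <- paste(sort(fam$records$record_id[fam$records$subfamily == "TIP"]),
                   collapse = "|")
  sup <- attr(b1, "support")
  expect_true(pip_key %in% names(sup))
  expect_gte(sup[[pip_key]], 95)
  # single replicate gives all-or-nothing supports
  b4 <- bootstrap_support(aln, 1, seed = 9)
  expect_true(all(attr(b4, "support") %in% c(0, 100)))
})
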