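# Distance phylogeny: p-distances with pairwise deletion, Poisson correction,
# neighbour joining (Saitou-Nei) with a pinned deterministic tie-break, and
# column-bootstrap support. Trees are returned as ape "phylo" objects so the
# usual Newick tooling applies.

#' Template-anchored star alignment
#'
#' Aligns every sequence to the template with [align_to_template()] and reads
#' off the residue at each template position, giving an alignment matrix with
#' one column per template site (insertions relative to the template are
#' dropped; unaligned sites are gaps). A desk-scale substitute for a full
#' multiple alignment; an externally produced MSA can be supplied to the
#' distance/bootstrap functions instead.
#'
#' @param sequences Named character vector of amino-acid strings.
#' @param template_annotation A [load_template()] object.
#' @return Character matrix (sequences x template positions) with `-` gaps.
#' @export
star_align <- function(sequences, template_annotation) {
  stopifnot(inherits(template_annotation, "template_annotation"))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named")
  L <- nchar(template_annotation$sequence)
  rows <- t(vapply(sequences, function(s) {
    map <- align_to_template(s, template_annotation$sequence)
    cs <- chars(s)
    ifelse(is.na(map), "-", cs[map])
  }, character(L)))
  rownames(rows) <- names(sequences)
  rows
}

#' Observed proportion of differing sites (pairwise deletion)
#'
#' Mismatches over compared sites, excluding any site where either row
#' carries a gap (`-`) or `X`.
#'
#' @param aligned_a,aligned_b Equal-length aligned rows (strings or character
#'   vectors).
#' @return Proportion in `[0, 1]`; `NA` with attribute `saturated = TRUE`
#'   when no site is comparable.
#' @export
#' @examples
#' p_distance("A-AA", "ATAA")  # 0 over 3 compared sites
p_distance <- function(aligned_a, aligned_b) {
  a <- if (length(aligned_a) == 1L) chars(aligned_a) else aligned_a
  b <- if (length(aligned_b) == 1L) chars(aligned_b) else aligned_b
  if (length(a) != length(b)) stop("aligned rows differ in length")
  use <- !(a %in% c("-", "X")) & !(b %in% c("-", "X"))
  if (!any(use)) return(structure(NA_real_, saturated = TRUE))
  sum(a[use] != b[use]) / sum(use)
}

#' Poisson multiple-hit correction
#'
#' `d = -ln(1 - p)`: corrects an observed proportion of differences for
#' unobserved multiple substitutions under a Poisson model.
#'
#' @param p Observed proportion(s) in `[0, 1)`.
#' @return Corrected distance(s); `p >= 1` yields `Inf` with attribute
#'   `saturated`, `p` outside `[0, 1]` is an error.
#' @export
poisson_correct <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p must lie in [0, 1]")
  d <- ifelse(!is.na(p) & p >= 1, Inf, -log(1 - p))
  if (any(is.infinite(d), na.rm = TRUE)) attr(d, "saturated") <- TRUE
  d
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @param alignment Character matrix (rows = sequences) as from
#'   [star_align()].
#' @param correction `"poisson"` or `"p"` (uncorrected).
#' @return Symmetric distance matrix with zero diagonal. Saturated or
#'   incomparable pairs are imputed to 1.25 x the largest finite distance
#'   and flagged in attribute `saturated_pairs`.
#' @export
distance_matrix <- function(alignment, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  n <- nrow(alignment)
  labs <- rownames(alignment)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- p_distance(alignment[i, ], alignment[j, ])
    v <- if (correction == "poisson") as.numeric(poisson_correct(p)) else as.numeric(p)
    if (is.na(v) || is.infinite(v)) {
      sat <- rbind(sat, c(labs[i], labs[j]))
      v <- NA_real_
    }
    d[i, j] <- d[j, i] <- v
  }
  if (!is.null(sat)) {
    mx <- max(d[is.finite(d)], na.rm = TRUE)
    d[is.na(d)] <- 1.25 * mx
    attr(d, "saturated_pairs") <- sat
    warning(nrow(sat), " saturated/incomparable pair(s) imputed")
  }
  d
}

#' Neighbour joining
#'
#' Saitou-Nei agglomeration on a distance matrix. Ties on the Q criterion
#' break deterministically to the lexicographically lowest label pair (an
#' internal node carries the lexicographically smallest label among its
#' leaves). Negative branch-length estimates are clamped to zero and listed
#' in attribute `clamped`. Exact on additive matrices.
#'
#' @param d Symmetric numeric matrix with labelled rows/columns (>= 3 taxa),
#'   zero diagonal, finite entries.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (is.null(rownames(d))) stop("d must have row/column labels")
  if (any(!is.finite(d))) stop("d contains non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop("d is not symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(d)
  nwk <- labs           # growing newick fragment per active node
  key <- labs           # tie-break label per active node
  clamped <- character()
  cl <- function(x, where) {
    if (x < 0) { clamped <<- c(clamped, where); 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    tie <- which(q - qmin <= 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    tie <- tie[tie[, 1] < tie[, 2], , drop = FALSE]
    pair_keys <- apply(tie, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]])); paste(k[1], k[2])
    })
    pick <- tie[order(pair_keys)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- cl(d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)), key[i])
    lj <- cl(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))), key[j])
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_key <- min(key[i], key[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    rownames(d) <- colnames(d) <- key
  }
  # final three nodes: closed-form three-point branch lengths
  la <- cl((d[1, 2] + d[1, 3] - d[2, 3]) / 2, key[1])
  lb <- cl((d[1, 2] + d[2, 3] - d[1, 3]) / 2, key[2])
  lc <- cl((d[1, 3] + d[2, 3] - d[1, 2]) / 2, key[3])
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(la), nwk[2], fmt(lb),
                 nwk[3], fmt(lc))
  tree <- ape::read.tree(text = txt)
  if (length(clamped)) attr(tree, "clamped") <- unique(clamped)
  tree
}

#' Unrooted bipartitions of a tree
#'
#' One canonical key per internal edge: the tip set on the side *not*
#' containing the alphabetically first tip, sorted and joined with `|`.
#' Trivial (single-tip) splits are excluded.
#'
#' @param tree An `ape::phylo`.
#' @return Character vector of split keys.
#' @export
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) {
    side <- sort(attr(parts, "labels")[idx])
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) return(NA_character_)
    paste(side, collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Is a set of tips monophyletic (as an unrooted split)?
#'
#' @param tree An `ape::phylo`.
#' @param tips Tip labels.
#' @return `TRUE` if some internal edge separates exactly `tips` from the
#'   rest (singletons and the full set are trivially `TRUE`).
#' @export
is_split <- function(tree, tips) {
  tips <- sort(tips)
  all_tips <- sort(tree$tip.label)
  if (length(tips) <= 1L || length(tips) >= length(all_tips) - 1L) return(TRUE)
  side <- if (all_tips[1] %in% tips) setdiff(all_tips, tips) else tips
  paste(side, collapse = "|") %in% tree_bipartitions(tree)
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-corrected NJ tree per replicate, and scores each internal edge of
#' the original tree by the percentage of replicates containing the same
#' bipartition. Replicate `r` draws under seed `seed + r`, so runs are
#' reproducible and order-independent.
#'
#' @param alignment Character matrix (rows = sequences).
#' @param n_reps Number of replicates (the study convention is 1000).
#' @param seed Integer base seed.
#' @param correction Passed to [distance_matrix()].
#' @return The original tree with integer percentage supports as
#'   `node.label` (root label empty) and a `support` attribute keyed by
#'   bipartition.
#' @export
bootstrap_support <- function(alignment, n_reps, seed, correction = "poisson") {
  if (ncol(alignment) < 2L) stop("alignment must have at least 2 columns")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  build <- function(aln) neighbor_joining(suppressWarnings(
    distance_matrix(aln, correction = correction)))
  tree <- build(alignment)
  splits <- tree_bipartitions(tree)
  hits <- setNames(numeric(length(splits)), splits)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    cols <- sample.int(ncol(alignment), replace = TRUE)
    rep_splits <- tree_bipartitions(build(alignment[, cols, drop = FALSE]))
    hits[splits %in% rep_splits] <- hits[splits %in% rep_splits] + 1
  }
  support <- round(100 * hits / n_reps)
  # attach as node labels: match each internal node's split to its support
  parts <- ape::prop.part(tree)
  labels_all <- attr(parts, "labels")
  anchor <- sort(tree$tip.label)[1]
  node_lab <- vapply(parts, function(idx) {
    side <- sort(labels_all[idx])
    if (anchor %in% side) side <- setdiff(sort(tree$tip.label), side)
    key <- paste(side, collapse = "|")
    if (key %in% names(support)) as.character(support[[key]]) else ""
  }, "")
  tree$node.label <- node_lab
  attr(tree, "support") <- support
  tree
}
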