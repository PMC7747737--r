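# Relative expression from Ct data: technical-replicate collapse, geNorm
# reference-gene stability, dilution-curve efficiency, 2^-ddCt
# quantification, max-100 rescaling with tier grouping, cross-platform
# concordance, and the group tests.
#
# The long Ct format used throughout: a data frame with columns
# gene, sample, tissue, bio_rep, tech_rep, ct  (ct NA = undetected).

check_ct_long <- function(ct) {
  need <- c("gene", "sample", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.na(ct$ct) & (ct$ct <= 0 | ct$ct > 45)))
    stop("Ct values must lie in (0, 45] or be NA (undetected)")
  invisible(ct)
}

#' Collapse technical replicates
#'
#' Averages the technical replicates of each (gene, sample) cell. With three
#' or more replicates, any replicate deviating more than `outlier_cycles`
#' from the cell median is dropped first (provided at least two survive);
#' dropped replicates are listed in attribute `outliers`. A cell whose
#' replicates are all missing stays `NA` (undetected).
#'
#' @param ct Long Ct data frame (see module description).
#' @param outlier_cycles Outlier cut-off in cycles (default 0.5).
#' @return Long data frame with one row per (gene, sample): columns `gene`,
#'   `sample`, `tissue`, `bio_rep` (if present) and mean `ct`.
#' @export
collapse_technical <- function(ct, outlier_cycles = 0.5) {
  check_ct_long(ct)
  keys <- c("gene", "sample", intersect(c("tissue", "bio_rep"), names(ct)))
  grp <- interaction(ct[keys[1:2]], drop = TRUE)
  outliers <- NULL
  rows <- lapply(split(ct, grp), function(cell) {
    v <- cell$ct
    keep <- !is.na(v)
    if (sum(keep) >= 3L) {
      med <- median(v[keep])
      dev <- abs(v - med) > outlier_cycles
      if (any(dev & keep) && sum(keep & !dev) >= 2L) {
        outliers <<- rbind(outliers, cell[keep & dev, , drop = FALSE])
        keep <- keep & !dev
      }
    }
    out <- cell[1, keys, drop = FALSE]
    out$ct <- if (any(keep)) mean(v[keep]) else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "outliers") <- outliers
  out
}

ct_wide <- function(ct) {
  # genes x samples matrix of (collapsed) Ct values
  genes <- unique(ct$gene); samples <- unique(ct$sample)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(ct$gene, genes), match(ct$sample, samples))] <- ct$ct
  m
}

#' geNorm expression-stability measure M
#'
#' For each candidate reference gene j, `M_j` is the mean over the other
#' candidates k of the standard deviation across samples of
#' `log2(Q_j / Q_k)`, where `Q = (1 + E)^(Ct_min - Ct)` is the relative
#' quantity. Perfectly co-regulated (ideally: constitutively stable) genes
#' give M = 0. The gene with the lowest M is selected (ties to input order).
#'
#' @param ct Long collapsed Ct data frame, or a genes x samples matrix.
#' @param candidates Candidate reference gene names (>= 2).
#' @param efficiencies Named amplification efficiencies E in `[0, 1]` scale
#'   (1 = perfect doubling); unmeasured candidates default to 1.
#' @return List of class `stability_result`: `m` (named M values, candidate
#'   order), `ranking` (most stable first), `selected`, `excluded` (dropped
#'   for undetected cells), and `pairwise_variation` from stepwise
#'   exclusion.
#' @export
genorm_m <- function(ct, candidates, efficiencies = NULL) {
  m <- if (is.matrix(ct)) ct else ct_wide(check_ct_long(ct))
  candidates <- as.character(candidates)
  if (length(candidates) < 2L) stop("need at least 2 candidate genes")
  miss <- setdiff(candidates, rownames(m))
  if (length(miss)) stop("candidates not in Ct table: ", paste(miss, collapse = ", "))
  if (ncol(m) < 2L) stop("need at least 2 samples")
  sub <- m[candidates, , drop = FALSE]
  undet <- rownames(sub)[apply(sub, 1, anyNA)]
  if (length(undet)) {
    warning("excluding candidate(s) undetected in some sample: ",
            paste(undet, collapse = ", "))
    candidates <- setdiff(candidates, undet)
    if (length(candidates) < 2L) stop("fewer than 2 usable candidates remain")
    sub <- m[candidates, , drop = FALSE]
  }
  eff <- setNames(rep(1, length(candidates)), candidates)
  if (!is.null(efficiencies)) {
    shared <- intersect(names(efficiencies), candidates)
    eff[shared] <- efficiencies[shared]
  }
  logq <- t(vapply(candidates, function(g)
    (min(sub[g, ]) - sub[g, ]) * log2(1 + eff[[g]]), numeric(ncol(sub))))
  mval <- vapply(candidates, function(j) {
    others <- setdiff(candidates, j)
    mean(vapply(others, function(k) sd(logq[j, ] - logq[k, ]), 1.0))
  }, 1.0)
  ranking <- candidates[order(mval)]
  # stepwise exclusion trace: worst gene removed until two remain
  trace <- list(); left <- candidates
  while (length(left) > 2L) {
    mv <- vapply(left, function(j) {
      mean(vapply(setdiff(left, j), function(k) sd(logq[j, ] - logq[k, ]), 1.0))
    }, 1.0)
    worst <- left[which.max(mv)]
    trace[[length(trace) + 1L]] <- list(removed = worst, m = mv)
    left <- setdiff(left, worst)
  }
  structure(list(m = mval, ranking = ranking,
                 selected = candidates[which.min(mval)],
                 excluded = undet, stepwise = trace, final_pair = left),
            class = "stability_result")
}

#' Amplification efficiency from a dilution series
#'
#' Least-squares slope of Ct against log10(relative concentration);
#' `E = 10^(-1/slope) - 1`, reported in percent. Assays outside
#' `[80, 120]`\% are flagged.
#'
#' @param ct_series Ct values (>= 3 points).
#' @param dilution_factors Relative template concentrations (e.g.
#'   `c(1, 0.1, 0.01)`), same length.
#' @return List of class `efficiency_estimate`: `slope`, `e_pct`,
#'   `r_squared`, `in_range`.
#' @export
efficiency_from_dilution <- function(ct_series, dilution_factors) {
  if (length(ct_series) != length(dilution_factors))
    stop("ct_series and dilution_factors differ in length")
  if (length(ct_series) < 3L) stop("need at least 3 dilution points")
  if (length(unique(dilution_factors)) < 2L)
    stop("dilution factors carry no variance")
  x <- log10(dilution_factors)
  fit <- lm(ct_series ~ x)
  slope <- unname(coef(fit)[2])
  e_pct <- (10^(-1 / slope) - 1) * 100
  structure(list(slope = slope, e_pct = e_pct,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 in_range = e_pct >= 80 && e_pct <= 120),
            class = "efficiency_estimate")
}

#' Relative quantification by 2^-ddCt
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per gene and tissue,
#' `ddCt = mean dCt(tissue) - mean dCt(calibrator tissue)` and the relative
#' quantity is `2^-ddCt` (or `(1+E)^-ddCt` when an efficiency is supplied).
#' Per-replicate quantities `2^-(dCt_i - mean dCt(calibrator))` provide the
#' standard error. A gene undetected in every sample of a tissue is reported
#' `detected = FALSE` with `NA` quantity.
#'
#' With `calibrator = NULL` the quantity is `base^-dCt` itself (normalized
#' to the reference gene, no per-gene calibrator), the scale on which
#' different genes can be compared and rescaled to relative units for tier
#' grouping.
#'
#' @param ct Long collapsed Ct data frame with a `tissue` column.
#' @param reference_gene Reference (housekeeping) gene; must be detected in
#'   every sample.
#' @param calibrator Calibrator tissue (default `"root"`), or `NULL` for
#'   reference-normalized quantities without a per-gene calibrator.
#' @param efficiencies Optional named per-gene efficiencies E (fraction); the
#'   quantification base becomes `1 + E` instead of 2.
#' @return Data frame: `gene`, `tissue`, `rq`, `se`, `n`, `detected`, plus
#'   attribute `replicates` with the per-sample quantities.
#' @export
ddct <- function(ct, reference_gene, calibrator = "root", efficiencies = NULL) {
  check_ct_long(ct)
  if (!"tissue" %in% names(ct)) stop("ct needs a tissue column")
  ref <- ct[ct$gene == reference_gene, ]
  if (!nrow(ref)) stop("reference gene not in table: ", reference_gene)
  if (anyNA(ref$ct)) stop("reference gene undetected in some sample(s)")
  refct <- setNames(ref$ct, ref$sample)
  targets <- setdiff(unique(ct$gene), reference_gene)
  if (!is.null(calibrator) && !calibrator %in% ct$tissue)
    stop("no samples from calibrator tissue: ", calibrator)
  reps <- NULL
  rows <- lapply(targets, function(g) {
    base <- if (!is.null(efficiencies) && g %in% names(efficiencies))
      1 + efficiencies[[g]] else 2
    sub <- ct[ct$gene == g, ]
    sub$dct <- sub$ct - refct[sub$sample]
    cal_mean <- if (is.null(calibrator)) 0 else {
      cal <- sub$dct[sub$tissue == calibrator]
      if (all(is.na(cal))) NA_real_ else mean(cal, na.rm = TRUE)
    }
    do.call(rbind, lapply(unique(sub$tissue), function(tis) {
      v <- sub$dct[sub$tissue == tis]
      det <- any(!is.na(v)) && !is.na(cal_mean)
      if (det) {
        ddct_t <- mean(v, na.rm = TRUE) - cal_mean
        rq <- base^(-ddct_t)
        per <- base^(-(v[!is.na(v)] - cal_mean))
        reps <<- rbind(reps, data.frame(gene = g, tissue = tis, rq = per,
                                        stringsAsFactors = FALSE))
        se <- if (length(per) > 1L) sd(per) / sqrt(length(per)) else NA_real_
        data.frame(gene = g, tissue = tis, rq = rq, se = se,
                   n = length(per), detected = TRUE, stringsAsFactors = FALSE)
      } else {
        data.frame(gene = g, tissue = tis, rq = NA_real_, se = NA_real_,
                   n = 0L, detected = FALSE, stringsAsFactors = FALSE)
      }
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  out
}

#' Rescale to relative units and assign expression tiers
#'
#' Rescales quantities so the most-expressed (gene, tissue) equals 100
#' relative units (ru) and assigns the three tiers used for expression
#' profiling: group 1 `(10, 100]`, group 2 `(1, 10]`, group 3 `[0, 1]`
#' (boundaries belong to the lower tier, so the tiers partition). Undetected
#' entries get ru 0 and fall in group 3. A per-gene tier (the tier of the
#' gene's maximum ru across tissues) is attached as attribute `gene_tiers`.
#'
#' @param results A [ddct()] data frame (columns `gene`, `tissue`, `rq`,
#'   `detected`).
#' @return `results` with added `ru` and `tier` columns.
#' @export
rescale_and_tier <- function(results) {
  stopifnot(all(c("gene", "rq") %in% names(results)))
  det <- if ("detected" %in% names(results)) results$detected else !is.na(results$rq)
  if (!any(det)) stop("no detected gene to anchor the rescaling")
  mx <- max(results$rq[det], na.rm = TRUE)
  results$ru <- ifelse(det, 100 * results$rq / mx, 0)
  tier_of <- function(ru) ifelse(ru > 10, "group1",
                                 ifelse(ru > 1, "group2", "group3"))
  results$tier <- tier_of(results$ru)
  per_gene <- vapply(split(results$ru, results$gene), max, 1.0)
  attr(results, "gene_tiers") <- setNames(tier_of(per_gene), names(per_gene))
  results
}

#' Cross-platform concordance of expression profiles
#'
#' Rescales each platform to its own maximum = 100 ru, then classifies each
#' shared gene by the per-tissue fold difference between platforms:
#' `concordant` (all tissues within `fold_threshold`), `tissue_specific`
#' (some but not all tissues), `discordant` (no tissue).
#'
#' @param qpcr,rnaseq Data frames `gene`, `tissue`, `value` (any
#'   platform-specific scale; each is rescaled internally).
#' @param fold_threshold Maximum fold difference still called concordant
#'   (default 3).
#' @param floor Rescaled values are floored at this ru before ratioing, so
#'   near-zero entries do not produce unstable folds (default 0.5).
#' @return List: `classes` (data frame `gene`, `class`, `concordant_tissues`),
#'   `table` (the merged rescaled values), `only_in_qpcr`, `only_in_rnaseq`.
#' @export
compare_platforms <- function(qpcr, rnaseq, fold_threshold = 3, floor = 0.5) {
  for (nm in c("gene", "tissue", "value")) {
    if (!nm %in% names(qpcr)) stop("qpcr lacks column ", nm)
    if (!nm %in% names(rnaseq)) stop("rnaseq lacks column ", nm)
  }
  rescale <- function(df) { df$ru <- 100 * df$value / max(df$value); df }
  q <- rescale(qpcr); r <- rescale(rnaseq)
  mg <- merge(q[c("gene", "tissue", "ru")], r[c("gene", "tissue", "ru")],
              by = c("gene", "tissue"), suffixes = c("_qpcr", "_rnaseq"))
  mg$fold <- pmax(mg$ru_qpcr, floor) / pmax(mg$ru_rnaseq, floor)
  mg$fold <- pmax(mg$fold, 1 / mg$fold)
  mg$concordant <- mg$fold <= fold_threshold
  classes <- do.call(rbind, lapply(split(mg, mg$gene), function(g) {
    cls <- if (all(g$concordant)) "concordant"
           else if (any(g$concordant)) "tissue_specific" else "discordant"
    data.frame(gene = g$gene[1], class = cls,
               concordant_tissues = paste(g$tissue[g$concordant], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(classes) <- NULL
  list(classes = classes, table = mg,
       only_in_qpcr = setdiff(unique(qpcr$gene), unique(rnaseq$gene)),
       only_in_rnaseq = setdiff(unique(rnaseq$gene), unique(qpcr$gene)))
}

#' Welch two-sample comparison of expression groups
#'
#' @param values_a,values_b Numeric replicate values (>= 2 each).
#' @return List: `t`, `df`, `p`, `significant` (alpha 0.05), `degenerate`
#'   (both groups have zero variance).
#' @export
group_test <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least 2 replicates per group")
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    return(list(t = NA_real_, df = NA_real_,
                p = if (mean(values_a) == mean(values_b)) 1 else 0,
                significant = mean(values_a) != mean(values_b),
                degenerate = TRUE))
  }
  ht <- t.test(values_a, values_b)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value <= 0.05, degenerate = FALSE)
}

#' One-way ANOVA with Tukey HSD across comparison groups
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (>= 3 levels for a useful Tukey step).
#' @return List: `anova_p`, `tukey` (data frame of pairwise contrasts with
#'   adjusted p), `significant_pairs`.
#' @export
tukey_groups <- function(values, groups) {
  groups <- factor(groups)
  fit <- aov(values ~ groups)
  av <- summary(fit)[[1]]
  tk <- as.data.frame(TukeyHSD(fit)$groups)
  tk$pair <- rownames(tk); rownames(tk) <- NULL
  list(anova_p = av[["Pr(>F)"]][1], tukey = tk,
       significant_pairs = tk$pair[tk$`p adj` <= 0.05])
}
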