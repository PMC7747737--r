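# Substrate-transport prediction as an auditable rule base: literature
# synthesis encoded as data (residue constraints -> substrates + evidence
# codes), with a generic engine and a regression diff against a published
# prediction column.

SUBSTRATES <- c("H2O", "CO2", "H2O2", "NH3", "urea", "B", "Si", "As", "Sb", "Gly")
RULE_POSITIONS <- c("LB", "LE", "H2", "H5", "LE1", "LE2", paste0("P", 1:5))

#' Load a transport rule base
#'
#' Reads a TSV of rules. Each rule carries a subfamily pattern (prefix match:
#' `PIP` matches `PIP1` and `PIP2`), residue constraints
#' (`pos=letters` pairs, comma-separated, bracket sets allowed: `H2=[AG]`;
#' positions `LB`/`LE` match the full 3-letter loop motif), `;`-separated
#' substrates with pairwise-aligned evidence codes, and a literature tag.
#'
#' @param path Rule TSV. Default: the packaged rule base reproducing the
#'   study's prediction column.
#' @return Data frame of class `rulebase` with a parsed `constraint_list`
#'   list-column.
#' @export
load_rulebase <- function(path = aquamip_extdata("rulebase_default.tsv")) {
  raw <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*#", raw) & nzchar(trimws(raw)))
  if (!length(body)) stop("empty rule file")
  tab <- read.delim(text = paste(raw[body], collapse = "\n"),
                    stringsAsFactors = FALSE)
  line_of <- body[-1]  # file line numbers of data rows
  need <- c("rule_id", "subfamily", "constraints", "substrates", "codes")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("rule file lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$rule_id))
    stop("duplicate rule ids: ",
         paste(unique(tab$rule_id[duplicated(tab$rule_id)]), collapse = ", "))
  tab$constraint_list <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ln <- line_of[i]
    cons <- parse_constraints(tab$constraints[i], line = ln)
    subs <- strsplit(tab$substrates[i], ";", fixed = TRUE)[[1]]
    codes <- strsplit(tab$codes[i], ";", fixed = TRUE)[[1]]
    bad <- setdiff(subs, SUBSTRATES)
    if (length(bad))
      stop(sprintf("line %d: unknown substrate token '%s'", ln, bad[1]))
    if (length(codes) != length(subs))
      stop(sprintf("line %d: %d substrates but %d code groups", ln,
                   length(subs), length(codes)))
    if (!nzchar(tab$subfamily[i]))
      stop(sprintf("line %d: empty subfamily pattern", ln))
    tab$constraint_list[[i]] <- cons
  }
  structure(tab, class = c("rulebase", "data.frame"))
}

parse_constraints <- function(x, line = NA) {
  x <- trimws(x)
  if (!nzchar(x)) return(list())
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(trimws(p), "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("line %s: malformed constraint '%s'", line, p))
    pos <- kv[1]
    if (!pos %in% RULE_POSITIONS)
      stop(sprintf("line %s: unknown position token '%s'", line, pos))
    val <- kv[2]
    allowed <- if (grepl("^\\[.*\\]$", val)) {
      chars(sub("^\\[(.*)\\]$", "\\1", val))
    } else val
    if (pos %in% c("LB", "LE")) {
      if (any(!grepl("^[A-Z]{3}$", allowed)))
        stop(sprintf("line %s: %s constraint must be 3-letter motif(s)", line, pos))
    } else if (any(!allowed %in% AA20)) {
      stop(sprintf("line %s: invalid residue letters in '%s'", line, p))
    }
    out[[pos]] <- allowed
  }
  out
}

signature_values <- function(signature) {
  if (inherits(signature, "residue_signature")) {
    c(LB = signature$npa_lb, LE = signature$npa_le,
      setNames(unname(signature$arr), c("H2", "H5", "LE1", "LE2")),
      setNames(unname(signature$froger), paste0("P", 1:5)))
  } else if (is.data.frame(signature) && nrow(signature) == 1L) {
    c(LB = signature$npa_lb, LE = signature$npa_le,
      H2 = signature$h2, H5 = signature$h5, LE1 = signature$le1,
      LE2 = signature$le2,
      setNames(unlist(signature[paste0("p", 1:5)], use.names = FALSE),
               paste0("P", 1:5)))
  } else stop("signature must be a residue_signature or a one-row table row")
}

rule_matches <- function(rule_subfamily, constraints, values, subfamily) {
  if (!startsWith(subfamily, rule_subfamily)) return(FALSE)
  for (pos in names(constraints)) {
    if (!values[[pos]] %in% constraints[[pos]]) return(FALSE)
  }
  TRUE
}

#' Predict transported substrates from a residue signature
#'
#' Fires every matching rule and returns the union of their substrate sets,
#' with the union of evidence codes per substrate. Water is emitted with
#' code `default` for every classified subfamily (published prediction
#' columns never list it) unless `include_water = FALSE`.
#'
#' @param signature A `residue_signature` or one row of a
#'   [load_residue_table()] frame.
#' @param subfamily Subfamily/group label of the protein (e.g. `PIP2`,
#'   `TIP`); prefix-matched against each rule's pattern.
#' @param rulebase A [load_rulebase()] object.
#' @param include_water Emit the implicit H2O prediction.
#' @return List of class `transport_prediction`: `substrates` (character),
#'   `codes` (named list), `rules_fired`, `unpredicted`.
#' @export
predict_transport <- function(signature, subfamily, rulebase,
                              include_water = TRUE) {
  stopifnot(inherits(rulebase, "rulebase"))
  values <- signature_values(signature)
  subs <- character(); codes <- list(); fired <- character()
  for (i in seq_len(nrow(rulebase))) {
    if (rule_matches(rulebase$subfamily[i], rulebase$constraint_list[[i]],
                     values, subfamily)) {
      fired <- c(fired, rulebase$rule_id[i])
      rs <- strsplit(rulebase$substrates[i], ";", fixed = TRUE)[[1]]
      rc <- strsplit(rulebase$codes[i], ";", fixed = TRUE)[[1]]
      for (k in seq_along(rs)) {
        s <- rs[k]
        codes[[s]] <- sort(unique(c(codes[[s]], rc[k])))
        if (!s %in% subs) subs <- c(subs, s)
      }
    }
  }
  unpredicted <- !length(subs)
  if (include_water) {
    subs <- c(subs, "H2O")
    codes[["H2O"]] <- "default"
  }
  structure(list(substrates = subs, codes = codes, rules_fired = fired,
                 unpredicted = unpredicted), class = "transport_prediction")
}

#' Predict transport for every gene in a residue table
#'
#' @param residues A [load_residue_table()] data frame.
#' @param rulebase A [load_rulebase()] object.
#' @param include_water Passed to [predict_transport()].
#' @return Named list of `transport_prediction`s, keyed by gene name.
#' @export
predict_all <- function(residues, rulebase, include_water = FALSE) {
  groups <- parse_gene_name(residues$gene_name)$group
  out <- lapply(seq_len(nrow(residues)), function(i) {
    predict_transport(residues[i, , drop = FALSE], groups[i], rulebase,
                      include_water = include_water)
  })
  setNames(out, residues$gene_name)
}

#' Diff predictions against a reference prediction column
#'
#' Per-gene symmetric difference of substrate sets (H2O excluded: published
#' columns never list water). An empty diff means the rule base reproduces
#' the reference exactly.
#'
#' @param predictions Named list of `transport_prediction`s.
#' @param reference A [load_residue_table()] frame with a `transport_set`
#'   column, or a named list of substrate character vectors.
#' @return List: `diff` (data frame gene/missing/extra for genes that
#'   disagree), `only_in_predictions`, `only_in_reference`, `n_compared`.
#' @export
diff_against_reference <- function(predictions, reference) {
  ref <- if (is.data.frame(reference)) {
    setNames(reference$transport_set, reference$gene_name)
  } else reference
  shared <- intersect(names(predictions), names(ref))
  rows <- lapply(shared, function(g) {
    pred <- setdiff(predictions[[g]]$substrates, "H2O")
    want <- setdiff(ref[[g]], "H2O")
    miss <- setdiff(want, pred); extra <- setdiff(pred, want)
    if (!length(miss) && !length(extra)) return(NULL)
    data.frame(gene_name = g, missing = paste(miss, collapse = ";"),
               extra = paste(extra, collapse = ";"), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  list(diff = if (length(rows)) do.call(rbind, rows) else
         data.frame(gene_name = character(), missing = character(),
                    extra = character(), stringsAsFactors = FALSE),
       only_in_predictions = setdiff(names(predictions), names(ref)),
       only_in_reference = setdiff(names(ref), names(predictions)),
       n_compared = length(shared))
}
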