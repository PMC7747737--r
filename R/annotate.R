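# MIP candidate curation and residue-signature extraction.
#
# The channel's two constrictions are read off each protein by positional
# transfer from an annotated template: a pairwise global alignment maps every
# annotated template site (NPA starts, ar/R filter, Froger positions) to a
# query coordinate, and the query residues at those coordinates form the
# signature. An independent degenerate-motif scan cross-checks the NPA sites.

# closure of the loop-motif variants seen across plant MIPs:
# {N,S} x P x {A,V,S,T,L,I}  (NPA, NPS, NPV, NPT, NPL, SPI, SPA, ...)
NPA_X1 <- c("N", "S")
NPA_X3 <- c("A", "V", "S", "T", "L", "I")

#' Scan a protein for NPA-type loop motifs
#'
#' Finds every window matching the degenerate loop-motif alphabet
#' `[NS]-P-[AVSTLI]` (the closure of the variants observed across plant MIP
#' loop B/loop E: NPA, NPS, NPV, NPT, NPL, SPI, SPA). Overlapping hits are
#' all reported.
#'
#' @param sequence Amino-acid string.
#' @return Data frame `position` (1-based window start, ascending), `motif`,
#'   `canonical` (`TRUE` for an exact NPA).
#' @export
#' @examples
#' scan_npa("AAANPAAAANPAAA")
scan_npa <- function(sequence) {
  validate_protein(sequence, allow_x = TRUE)
  m <- gregexpr("(?=([NS]P[AVSTLI]))", sequence, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(position = integer(), motif = character(),
                      canonical = logical(), stringsAsFactors = FALSE))
  pos <- as.integer(m)
  motif <- substring(sequence, pos, pos + 2L)
  data.frame(position = pos, motif = motif, canonical = motif == "NPA",
             stringsAsFactors = FALSE)
}

has_dual_npa <- function(sequence) {
  hits <- scan_npa(sequence)
  half <- nchar(sequence) / 2
  any(hits$position <= half) && any(hits$position > half)
}

#' Curate MIP candidate sequences
#'
#' Applies the study's elimination rules to a candidate pool:
#' \itemize{
#'   \item `missing_npa`: fewer than two loop motifs in distinct halves of
#'     the sequence (fragments carrying only one re-entrant loop,
#'     NPA-less transcript variants);
#'   \item `transcript_variant`: as `missing_npa`, but the record shares a
#'     `gene_name` with a retained record;
#'   \item `partial_duplicate`: aligns over its full length to a longer (or
#'     equal, earlier-retained) record at `>= identity_threshold` identity.
#' }
#'
#' @param records Data frame with `record_id`, `sequence`, optionally
#'   `gene_name`.
#' @param identity_threshold Full-length identity above which a shorter
#'   record is a redundant partial copy. Default 0.98 (the study's
#'   "at least 98--99\% identity").
#' @return List of class `curation_report`: `retained` (record ids),
#'   `discarded` (data frame `record_id`, `reason`).
#' @export
curate <- function(records, identity_threshold = 0.98) {
  stopifnot(all(c("record_id", "sequence") %in% names(records)))
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  ok_npa <- vapply(records$sequence, has_dual_npa, TRUE, USE.NAMES = FALSE)
  # among dual-NPA records, longest-first greedy retention; shorter full-length
  # near-identical copies are redundant partials
  cand <- records[ok_npa, , drop = FALSE]
  cand <- cand[order(-nchar(cand$sequence)), , drop = FALSE]
  retained <- character()
  retained_seq <- character()
  dup <- character()
  for (i in seq_len(nrow(cand))) {
    s <- cand$sequence[i]
    is_dup <- FALSE
    for (r in retained_seq) {
      if (nchar(s) > nchar(r)) next
      pid <- full_length_identity(s, r)
      if (pid >= identity_threshold) { is_dup <- TRUE; break }
    }
    if (is_dup) dup <- c(dup, cand$record_id[i])
    else {
      retained <- c(retained, cand$record_id[i])
      retained_seq <- c(retained_seq, s)
    }
  }
  # restore input order for the retained list
  retained <- records$record_id[records$record_id %in% retained]
  bad <- records[!ok_npa, , drop = FALSE]
  retained_genes <- if ("gene_name" %in% names(records))
    records$gene_name[records$record_id %in% retained] else character()
  reason_bad <- rep("missing_npa", nrow(bad))
  if ("gene_name" %in% names(bad))
    reason_bad[!is.na(bad$gene_name) & bad$gene_name %in% retained_genes] <-
      "transcript_variant"
  discarded <- rbind(
    data.frame(record_id = bad$record_id, reason = reason_bad,
               stringsAsFactors = FALSE),
    data.frame(record_id = dup, reason = rep("partial_duplicate", length(dup)),
               stringsAsFactors = FALSE))
  discarded <- discarded[match(intersect(records$record_id, discarded$record_id),
                               discarded$record_id), , drop = FALSE]
  rownames(discarded) <- NULL
  structure(list(retained = retained, discarded = discarded),
            class = "curation_report")
}

# identity of the shorter sequence aligned end-to-end within the longer
full_length_identity <- function(short, long) {
  aln <- Biostrings::pairwiseAlignment(short, long, type = "global-local",
                                       substitutionMatrix = blosum62(),
                                       gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / nchar(short)
}

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' Map template positions onto a query by global alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps: open 10,
#' extend 0.5) of the template against the query; the traceback is the
#' deterministic one produced by [Biostrings::pairwiseAlignment()].
#'
#' @param query,template Amino-acid strings.
#' @return Integer vector of length `nchar(template)`: for each template
#'   position the aligned 1-based query position, or `NA` where the template
#'   position falls in a deletion.
#' @export
align_to_template <- function(query, template) {
  validate_protein(query, allow_x = TRUE, what = "query")
  validate_protein(template, allow_x = TRUE, what = "template")
  aln <- Biostrings::pairwiseAlignment(template, query, type = "global",
                                       substitutionMatrix = blosum62(),
                                       gapOpening = 10, gapExtension = 0.5)
  pat <- chars(as.character(Biostrings::alignedPattern(aln)))
  sub <- chars(as.character(Biostrings::alignedSubject(aln)))
  map <- rep(NA_integer_, nchar(template))
  tpos <- 0L; qpos <- 0L
  for (k in seq_along(pat)) {
    tp <- pat[k] != "-"; sp <- sub[k] != "-"
    if (tp) tpos <- tpos + 1L
    if (sp) qpos <- qpos + 1L
    if (tp && sp) map[tpos] <- qpos
  }
  map
}

#' Extract the residue signature of a query protein
#'
#' Reads the query residues at the template-mapped positions of the loop-B
#' and loop-E NPA motifs, the ar/R selectivity filter (H2, H5, LE1, LE2) and
#' the Froger positions (P1-P5). If the aligned 3-mer at a mapped loop start
#' is not a degenerate loop motif but [scan_npa()] finds one within 5
#' residues of the mapped site, the scanned motif wins (alignment jitter near
#' the re-entrant loops) and the event is recorded in `notes`.
#'
#' @param query Amino-acid string.
#' @param template_annotation A [load_template()] object.
#' @return List of class `residue_signature`: `npa_lb`, `npa_le` (3-letter
#'   motifs, `-` where unaligned), `arr` (4 residues), `froger` (5 residues),
#'   `coords` (named query coordinates, `NA` = unaligned), `low_confidence`
#'   (more than 2 named sites unaligned), `notes`.
#' @export
extract_signature <- function(query, template_annotation) {
  stopifnot(inherits(template_annotation, "template_annotation"))
  pos <- template_annotation$positions
  map <- align_to_template(query, template_annotation$sequence)
  qc <- chars(query)
  notes <- character()
  at <- function(qpos) ifelse(is.na(qpos), "-", qc[qpos])

  get_motif <- function(start_name) {
    tstart <- pos[[start_name]]
    qstart <- map[tstart]
    motif <- paste(vapply(map[tstart + 0:2], at, ""), collapse = "")
    is_loop <- grepl("^[NS]P[AVSTLI]$", motif)
    if (!is_loop) {
      hits <- scan_npa(query)
      anchor <- if (!is.na(qstart)) qstart else {
        near <- map[max(1, tstart - 5):min(length(map), tstart + 5)]
        if (all(is.na(near))) NA_integer_ else round(mean(near, na.rm = TRUE))
      }
      if (!is.na(anchor) && nrow(hits)) {
        close <- hits[abs(hits$position - anchor) <= 5, , drop = FALSE]
        if (nrow(close)) {
          close <- close[which.min(abs(close$position - anchor)), ]
          notes <<- c(notes, sprintf(
            "%s: aligned 3-mer '%s' replaced by scanned motif '%s' at query %d",
            start_name, motif, close$motif, close$position))
          return(list(motif = close$motif, qstart = close$position))
        }
      }
    }
    list(motif = motif, qstart = qstart)
  }

  lb <- get_motif("npa_lb")
  le <- get_motif("npa_le")
  arr_names <- c("H2", "H5", "LE1", "LE2")
  fro_names <- paste0("P", 1:5)
  arr_q <- map[pos[arr_names]]
  fro_q <- map[pos[fro_names]]
  coords <- c(npa_lb = lb$qstart, npa_le = le$qstart,
              setNames(arr_q, arr_names), setNames(fro_q, fro_names))
  structure(list(
    npa_lb = lb$motif, npa_le = le$motif,
    arr = setNames(vapply(arr_q, at, ""), arr_names),
    froger = setNames(vapply(fro_q, at, ""), fro_names),
    coords = coords,
    low_confidence = sum(is.na(coords)) > 2L,
    notes = notes), class = "residue_signature")
}

#' @export
format.residue_signature <- function(x, ...) {
  sprintf("%s/%s  ar/R: %s  FP: %s%s",
          x$npa_lb, x$npa_le, paste(x$arr, collapse = ""),
          paste(x$froger, collapse = ""),
          if (x$low_confidence) "  [low confidence]" else "")
}

#' @export
print.residue_signature <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Tabulate residue signatures
#'
#' Flattens a list of signatures into a data frame with the residue table's
#' column order (loop motifs, H2, H5, LE1, LE2, P1-P5).
#'
#' @param signatures Named list of `residue_signature` objects.
#' @return Data frame, one row per signature.
#' @export
signature_table <- function(signatures) {
  rows <- lapply(names(signatures), function(id) {
    s <- signatures[[id]]
    cbind(data.frame(gene_name = id, npa_lb = s$npa_lb, npa_le = s$npa_le,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(s$arr, c("h2", "h5", "le1", "le2"))),
                        stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(s$froger, paste0("p", 1:5))),
                        stringsAsFactors = FALSE),
          data.frame(low_confidence = s$low_confidence))
  })
  do.call(rbind, rows)
}

#' Classify a query into an aquaporin subfamily
#'
#' Scores the query against every member of a labelled reference panel by
#' global-alignment percent identity and calls the subfamily of the best
#' scorer. Ties break deterministically to the earlier panel member.
#'
#' @param query Amino-acid string.
#' @param panel Data frame `record_id`, `subfamily`, `sequence`.
#' @param threshold Similarity below which the call is `unclassified`
#'   (default 0.35, below random-homology expectation for MIPs).
#' @return List of class `subfamily_call`: `label`, `best_reference`,
#'   `score` (in `[0, 1]`), `margin` (gap to the best other subfamily).
#' @export
classify_subfamily <- function(query, panel, threshold = 0.35) {
  if (is.null(panel) || !nrow(panel)) stop("reference panel is empty")
  stopifnot(all(c("record_id", "subfamily", "sequence") %in% names(panel)))
  scores <- vapply(panel$sequence, function(ref) {
    aln <- Biostrings::pairwiseAlignment(query, ref, type = "global",
                                         substitutionMatrix = blosum62(),
                                         gapOpening = 10, gapExtension = 0.5)
    Biostrings::pid(aln, type = "PID1") / 100
  }, 1.0, USE.NAMES = FALSE)
  best <- which.max(scores)  # first max: panel-order tie-break
  label <- panel$subfamily[best]
  others <- scores[panel$subfamily != label]
  margin <- if (length(others)) scores[best] - max(others) else scores[best]
  call_label <- if (scores[best] < threshold) "unclassified" else label
  structure(list(label = call_label, best_reference = panel$record_id[best],
                 score = scores[best], margin = margin,
                 scores = setNames(scores, panel$record_id)),
            class = "subfamily_call")
}

#' Family-level summaries of a MIP census
#'
#' Per-subfamily and per-chromosome gene counts, the tally of predicted
#' transmembrane-helix numbers, and per-subfamily length/pI/Mw statistics.
#' Statistics are computed at full precision; round at display time.
#'
#' @param features A [load_feature_table()] data frame.
#' @return List: `subfamily_counts`, `group_counts`, `chromosome_counts`,
#'   `tmh_tally`, `subfamily_stats` (min/max/median length, mean pI, mean
#'   Mw).
#' @export
summarize_family <- function(features) {
  p <- parse_gene_name(features$gene_name)
  subfam <- factor(p$subfamily, levels = SUBFAMILY_ORDER)
  out <- list(
    subfamily_counts = table(subfam),
    group_counts = table(p$group),
    chromosome_counts = table(features$chromosome),
    tmh_tally = if ("tmh" %in% names(features)) table(features$tmh) else NULL)
  if (all(c("length_aa", "pi", "mw_kda") %in% names(features))) {
    sp <- split(features, subfam)
    out$subfamily_stats <- do.call(rbind, lapply(names(sp), function(s) {
      f <- sp[[s]]
      if (!nrow(f)) return(NULL)
      data.frame(subfamily = s, n = nrow(f),
                 min_length = min(f$length_aa), max_length = max(f$length_aa),
                 median_length = median(f$length_aa),
                 mean_pi = mean(f$pi), mean_mw = mean(f$mw_kda),
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Count records with a given residue at a named signature position
#'
#' @param residues A [load_residue_table()] data frame (or [signature_table()]
#'   output).
#' @param position Column name: one of `npa_lb`, `npa_le`, `h2`, `h5`, `le1`,
#'   `le2`, `p1`..`p5`.
#' @param residue Single letter (or full motif for the loop columns).
#' @param genes Optional subset of `gene_name`s.
#' @return Integer count.
#' @export
#' @examples
#' res <- load_residue_table(aquamip_extdata("table3_residues.tsv"))
#' pips <- res$gene_name[grepl("PIP", res$gene_name)]
#' count_residue_at(res, "p1", "Q", genes = pips)
count_residue_at <- function(residues, position, residue, genes = NULL) {
  if (!position %in% names(residues)) stop("unknown position column: ", position)
  keep <- if (is.null(genes)) rep(TRUE, nrow(residues))
          else residues$gene_name %in% genes
  sum(residues[[position]][keep] == residue, na.rm = TRUE)
}
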