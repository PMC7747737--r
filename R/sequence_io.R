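# Reading/writing sequence and table inputs: FASTA, locus strings, and the
# packaged mirrors of the study's gene-feature / residue / primer tables.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Data frame with one row per entry: `record_id` (first whitespace
#'   token of the header), `description` (remainder), `sequence` (uppercased,
#'   terminal stop `*` stripped).
#' @details Duplicate record ids and empty sequences are errors naming the
#'   offending entries; an empty file yields a zero-row frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(record_id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(record_id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  starts <- grep("^>", lines)
  if (!length(starts) || starts[1] != 1L)
    stop("malformed FASTA: first non-blank line is not a header in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  headers <- sub("^>", "", lines[starts])
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S+", "", headers))
  seqs <- vapply(seq_along(starts), function(i) {
    if (ends[i] < starts[i] + 1L) return("")
    paste(lines[(starts[i] + 1L):ends[i]], collapse = "")
  }, "")
  seqs <- toupper(gsub("\\s", "", seqs))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(ids)))
    stop("malformed FASTA header (empty id) at entry ", which(!nzchar(ids))[1])
  if (any(!nzchar(seqs)))
    stop("empty sequence for entry: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate record ids: ", paste(dup, collapse = ", "))
  data.frame(record_id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records Data frame with `record_id` and `sequence` (optionally
#'   `description`).
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("record_id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$record_id[i]
    if (!is.null(records$description) && nzchar(records$description[i]))
      hdr <- paste(hdr, records$description[i])
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a genomic locus string
#'
#' Parses strings of the form `"chr10: 9455124 .. 9456876 (-)"` as printed in
#' the study's feature table. Both the unicode minus and the ASCII hyphen are
#' accepted for the reverse strand; coordinates are 1-based inclusive.
#'
#' @param raw Character vector of locus strings.
#' @return Data frame with `chromosome`, `start`, `end`, `strand` (`+`/`-`).
#' @export
#' @examples
#' parse_locus("chr05: 4877174 .. 4878743 (+)")
parse_locus <- function(raw) {
  norm <- normalize_minus(raw)
  m <- regmatches(norm, regexec(
    "^(chr[0-9]+)\\s*:\\s*([0-9]+)\\s*\\.\\.\\s*([0-9]+)\\s*\\(([+-])\\)$", norm))
  bad <- which(vapply(m, length, 1L) == 0L)
  if (length(bad))
    stop("unparseable locus string: ", paste(raw[bad], collapse = "; "))
  out <- data.frame(
    chromosome = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE)
  if (any(out$start > out$end))
    stop("locus start > end in: ", paste(raw[out$start > out$end], collapse = "; "))
  out
}

#' Format a parsed locus back to its canonical string
#'
#' Inverse of [parse_locus()] on canonical strings (ASCII strand).
#'
#' @param chromosome,start,end,strand Parsed locus fields.
#' @return Character vector of locus strings.
#' @export
format_locus <- function(chromosome, start, end, strand) {
  sprintf("%s: %d .. %d (%s)", chromosome, start, end, strand)
}

#' Load a gene-feature table
#'
#' Reads a TSV mirroring the study's per-gene feature table (gene name, locus
#' string, exon count, mRNA length, protein length, Mw, pI, predicted
#' transmembrane-helix count). `gene_name` and `locus` are mandatory; other
#' columns are optional and missing cells stay `NA`, never zero.
#'
#' @param path TSV with a header row.
#' @return Data frame of records with parsed locus columns, ordered as in the
#'   input. Rows whose locus fails to parse are dropped and reported in the
#'   `"row_errors"` attribute. Attribute `"subfamily_counts"` carries the
#'   loader's count report.
#' @export
load_feature_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  need <- c("gene_name", "locus")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("feature table lacks mandatory column(s): ", paste(miss, collapse = ", "))
  loc <- lapply(tab$locus, function(x) tryCatch(parse_locus(x), error = function(e) e))
  bad <- vapply(loc, inherits, TRUE, what = "error")
  errors <- data.frame(row = which(bad), gene_name = tab$gene_name[bad],
                       message = vapply(loc[bad], conditionMessage, ""),
                       stringsAsFactors = FALSE)
  tab <- tab[!bad, , drop = FALSE]
  locdf <- do.call(rbind, loc[!bad])
  out <- cbind(tab, locdf)
  for (col in c("exons", "mrna_bp", "length_aa", "tmh"))
    if (col %in% names(out)) out[[col]] <- suppressWarnings(as.integer(normalize_minus(as.character(out[[col]]))))
  for (col in c("mw_kda", "pi"))
    if (col %in% names(out)) out[[col]] <- suppressWarnings(as.numeric(normalize_minus(as.character(out[[col]]))))
  counts <- table(factor(parse_gene_name(out$gene_name)$subfamily, levels = SUBFAMILY_ORDER))
  attr(out, "row_errors") <- errors
  attr(out, "subfamily_counts") <- counts
  if (nrow(errors))
    warning(nrow(errors), " row(s) with malformed locus dropped (see attr 'row_errors')")
  message("loaded ", nrow(out), " records; subfamily counts: ",
          paste(names(counts), counts, sep = "=", collapse = " "))
  out
}

#' Load a residue-signature table
#'
#' Reads a TSV mirroring the study's functional-residue table: per gene the
#' loop-B/loop-E NPA-type motifs, the four ar/R filter residues (H2, H5, LE1,
#' LE2), the five Froger positions (P1-P5), and the published transport
#' prediction encoded as `substrate:codes` pairs separated by `;` (`-` for
#' no prediction).
#'
#' @param path TSV with a header row.
#' @return Data frame; the transport column is kept verbatim, with a parsed
#'   list-column `transport_set` of substrate character vectors.
#' @export
load_residue_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_name", "npa_lb", "npa_le", "h2", "h5", "le1", "le2",
            paste0("p", 1:5))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("residue table lacks column(s): ", paste(miss, collapse = ", "))
  if ("transport" %in% names(tab)) {
    tab$transport_set <- lapply(tab$transport, parse_transport_field)
  }
  tab
}

parse_transport_field <- function(x) {
  x <- trimws(normalize_minus(x))
  if (is.na(x) || x %in% c("", "-")) return(character())
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  vapply(strsplit(parts, ":", fixed = TRUE), `[`, "", 1L)
}

#' Load a primer table
#'
#' Reads a TSV mirroring the study's primer table: per gene the forward and
#' reverse primer (5'->3'), amplicon size, the published free-energy panel
#' (full-primer dG, self-dimer dG per primer, hetero-dimer dG, kcal/mol),
#' assay efficiency and cycling conditions. Unicode minus signs are
#' normalized; the tokens `Non` (no dimer found), `NM` (not measured) and `-`
#' become `NA`.
#'
#' @param path TSV with a header row.
#' @return Data frame with numeric dG/efficiency columns and uppercase primer
#'   sequences.
#' @export
load_primer_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_name", "forward", "reverse")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("primer table lacks column(s): ", paste(miss, collapse = ", "))
  numify <- function(x) {
    x <- normalize_minus(as.character(x))
    x[x %in% c("", "-", "Non", "NM", "NA")] <- NA
    as.numeric(x)
  }
  for (col in intersect(c("product_bp", "dg_primer_f", "dg_primer_r", "dg_self_f",
                          "dg_self_r", "dg_hetero", "efficiency_pct",
                          "tm_melting_c", "ta_annealing_c"), names(tab)))
    tab[[col]] <- numify(tab[[col]])
  tab$forward <- toupper(trimws(tab$forward))
  tab$reverse <- toupper(trimws(tab$reverse))
  tab
}

#' Load the annotated residue-transfer template
#'
#' Reads a template FASTA plus its annotation TSV (named 1-based positions of
#' the loop-B/loop-E NPA starts, the ar/R filter sites H2/H5/LE1/LE2 and the
#' Froger positions P1-P5) and validates that the annotation is internally
#' consistent with the sequence (both annotated triplets read `NPA` on the
#' template; all positions within range and mutually disjoint).
#'
#' @param fasta Template FASTA (single entry). Default: the packaged
#'   synthetic PIP-like scaffold.
#' @param annotation Annotation TSV with columns `name`, `position`.
#' @return List of class `template_annotation`: `template_id`, `sequence`,
#'   `positions` (named integer vector).
#' @export
load_template <- function(fasta = aquamip_extdata("template_mip_synthetic.fasta"),
                          annotation = aquamip_extdata("template_annotation_synthetic.tsv")) {
  rec <- read_fasta(fasta)
  if (nrow(rec) != 1L) stop("template FASTA must contain exactly one entry")
  ann <- read.delim(annotation, comment.char = "#", stringsAsFactors = FALSE)
  pos <- setNames(as.integer(ann$position), ann$name)
  need <- c("npa_lb", "npa_le", "H2", "H5", "LE1", "LE2", paste0("P", 1:5))
  miss <- setdiff(need, names(pos))
  if (length(miss)) stop("template annotation lacks: ", paste(miss, collapse = ", "))
  seq <- rec$sequence
  if (any(pos < 1L | pos > nchar(seq))) stop("annotation positions outside template")
  trip <- function(p) substr(seq, p, p + 2L)
  if (trip(pos[["npa_lb"]]) != "NPA" || trip(pos[["npa_le"]]) != "NPA")
    stop("template triplets at annotated NPA starts must read NPA")
  expanded <- c(pos[["npa_lb"]] + 0:2, pos[["npa_le"]] + 0:2,
                pos[c("H2", "H5", "LE1", "LE2", paste0("P", 1:5))])
  if (anyDuplicated(expanded)) stop("annotated position sets overlap")
  structure(list(template_id = rec$record_id, sequence = seq, positions = pos),
            class = "template_annotation")
}
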