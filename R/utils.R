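# shared helpers: unicode normalization, gene-name parsing, amino-acid alphabet

AA20 <- c("A","R","N","D","C","E","Q","G","H","I","L","K","M","F","P","S","T","W","Y","V")

SUBFAMILY_ORDER <- c("PIP", "TIP", "NIP", "SIP", "XIP")

# tables printed with typographic minus / dashes; normalize before parsing numbers
normalize_minus <- function(x) {
  x <- gsub("−", "-", x)        # unicode minus
  x <- gsub("–|—", "-", x) # en/em dash
  gsub("\\s+", " ", trimws(x))
}

#' Parse an aquaporin gene name
#'
#' Splits names of the form `CmPIP1;1` (species prefix optional) into
#' subfamily (`PIP`), group (`PIP1`) and member number. Used for subfamily
#' tallies and for deterministic table ordering.
#'
#' @param gene_name Character vector of gene names.
#' @return Data frame with columns `gene_name`, `subfamily`, `group`,
#'   `group_num`, `member_num`. Unparseable names yield `NA` fields.
#' @export
#' @examples
#' parse_gene_name(c("CmPIP1;1", "CmXIP1;1"))
parse_gene_name <- function(gene_name) {
  m <- regmatches(gene_name,
                  regexec("^(?:[A-Z][a-z])?(PIP|TIP|NIP|SIP|XIP)(\\d+);(\\d+)$", gene_name))
  sub <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, "")
  gnum <- vapply(m, function(g) if (length(g)) as.integer(g[3]) else NA_integer_, 1L)
  mnum <- vapply(m, function(g) if (length(g)) as.integer(g[4]) else NA_integer_, 1L)
  data.frame(gene_name = gene_name, subfamily = sub,
             group = ifelse(is.na(sub), NA_character_, paste0(sub, gnum)),
             group_num = gnum, member_num = mnum, stringsAsFactors = FALSE)
}

#' Deterministic gene-name ordering
#'
#' Orders by subfamily (PIP < TIP < NIP < SIP < XIP), then numeric group,
#' then numeric member, reproducing the layout of the study tables.
#'
#' @param gene_name Character vector.
#' @return Integer permutation, as [order()].
#' @export
gene_order <- function(gene_name) {
  p <- parse_gene_name(gene_name)
  order(match(p$subfamily, SUBFAMILY_ORDER), p$group_num, p$member_num, gene_name)
}

validate_protein <- function(sequence, allow_x = TRUE, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop(what, " must be a single non-empty string")
  ok <- AA20
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), ok)
  if (length(bad))
    stop(what, " contains non-amino-acid characters: ", paste(bad, collapse = ", "))
  invisible(sequence)
}

validate_dna <- function(strand, what = "strand") {
  if (length(strand) != 1L || is.na(strand) || !nzchar(strand))
    stop(what, " must be a single non-empty string")
  bad <- setdiff(unique(strsplit(toupper(strand), "")[[1]]), c("A", "C", "G", "T"))
  if (length(bad))
    stop(what, " contains non-ACGT characters: ", paste(bad, collapse = ", "))
  invisible(toupper(strand))
}

chars <- function(x) strsplit(x, "")[[1]]
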