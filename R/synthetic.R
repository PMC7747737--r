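# Deterministic generators: MIP-like protein families with planted residue
# signatures, study-shaped candidate pools for curation, Ct matrices with
# known fold-changes, and paired-platform expression tables with known
# concordance classes. Each generator runs on its own seeded RNG stream and
# returns a ground-truth table; downstream recovery tests read truth only
# from those tables.

# subfamily-typical residue signatures used as planting defaults; each entry:
# loop-B motif, loop-E motif, ar/R (H2,H5,LE1,LE2), Froger P1-P5
SUBFAMILY_SIGNATURES <- list(
  PIP1 = list(lb = "NPA", le = "NPA", arr = c("F","H","T","R"), froger = c("Q","S","A","F","W")),
  PIP2 = list(lb = "NPA", le = "NPA", arr = c("F","H","T","R"), froger = c("Q","S","A","F","W")),
  TIP  = list(lb = "NPA", le = "NPA", arr = c("H","I","A","V"), froger = c("T","A","S","Y","W")),
  NIP  = list(lb = "NPA", le = "NPV", arr = c("G","S","G","R"), froger = c("L","T","A","Y","F")),
  SIP  = list(lb = "NPT", le = "NPA", arr = c("F","I","P","N"), froger = c("M","A","A","Y","W")),
  XIP  = list(lb = "SPI", le = "SPA", arr = c("I","I","V","R"), froger = c("M","C","A","F","W")))

annotated_sites <- function(template_annotation) {
  pos <- template_annotation$positions
  c(pos[["npa_lb"]] + 0:2, pos[["npa_le"]] + 0:2,
    pos[c("H2", "H5", "LE1", "LE2", paste0("P", 1:5))])
}

# substitutions at `rate` outside the protected sites; vector in, vector out
mutate_background <- function(cs, rate, protected) {
  if (rate <= 0) return(cs)
  idx <- setdiff(seq_along(cs), protected)
  hit <- idx[stats::runif(length(idx)) < rate]
  for (i in hit) cs[i] <- sample(setdiff(AA20, cs[i]), 1L)
  cs
}

plant_signature <- function(cs, sig, pos) {
  cs[pos[["npa_lb"]] + 0:2] <- chars(sig$lb)
  cs[pos[["npa_le"]] + 0:2] <- chars(sig$le)
  cs[pos[c("H2", "H5", "LE1", "LE2")]] <- sig$arr
  cs[pos[paste0("P", 1:5)]] <- sig$froger
  cs
}

#' Generate a MIP-like protein family with planted signatures
#'
#' Derives one founder per requested subfamily from the annotated template
#' (subfamily signature planted at the annotated sites, then founder-level
#' background divergence), then each member from its founder by background
#' substitutions and optional short indels. Indels avoid a +/-2 window
#' around every annotated site, so planted-residue recovery failures isolate
#' alignment errors rather than generator collisions. The truth table
#' records every planted residue with its final coordinate.
#'
#' @param subfamilies Character vector, one subfamily label per sequence
#'   (names of `SUBFAMILY_SIGNATURES`: PIP1, PIP2, TIP, NIP, SIP, XIP).
#' @param template_annotation A [load_template()] object.
#' @param mutation_rate Per-site background substitution probability for
#'   members (default 0.05; `[0, 0.3]`).
#' @param indel_rate Expected indels per member sequence (default 0).
#' @param founder_rate Founder divergence from the template (default 0.25).
#' @param planted Optional named list overriding the per-subfamily signature
#'   defaults.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @return List: `records` (data frame `record_id`, `subfamily`,
#'   `sequence`), `founders`, `truth` (data frame `record_id`, `site`,
#'   `residue`, `coordinate`).
#' @export
generate_family <- function(subfamilies, template_annotation,
                            mutation_rate = 0.05, indel_rate = 0,
                            founder_rate = 0.25, planted = NULL, seed = 1L) {
  stopifnot(inherits(template_annotation, "template_annotation"))
  if (mutation_rate < 0 || mutation_rate > 0.3)
    stop("mutation_rate must lie in [0, 0.3]")
  bad <- setdiff(unique(subfamilies), names(SUBFAMILY_SIGNATURES))
  if (length(bad)) stop("unknown subfamily label(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  pos <- template_annotation$positions
  prot_sites <- annotated_sites(template_annotation)
  prot_window <- unique(unlist(lapply(prot_sites, function(p) (p - 2):(p + 2))))
  tmpl <- chars(template_annotation$sequence)

  founders <- lapply(unique(subfamilies), function(sf) {
    sig <- if (!is.null(planted) && sf %in% names(planted)) planted[[sf]]
           else SUBFAMILY_SIGNATURES[[sf]]
    plant_signature(mutate_background(tmpl, founder_rate, prot_sites), sig, pos)
  })
  names(founders) <- unique(subfamilies)

  site_names <- c("npa_lb_1", "npa_lb_2", "npa_lb_3", "npa_le_1", "npa_le_2",
                  "npa_le_3", "H2", "H5", "LE1", "LE2", paste0("P", 1:5))
  site_pos <- c(pos[["npa_lb"]] + 0:2, pos[["npa_le"]] + 0:2,
                pos[c("H2", "H5", "LE1", "LE2", paste0("P", 1:5))])

  counter <- stats::setNames(rep(0L, length(founders)), names(founders))
  records <- NULL; truth <- NULL
  for (sf in subfamilies) {
    counter[sf] <- counter[sf] + 1L
    id <- sprintf("syn%s_%02d", sf, counter[sf])
    cs <- mutate_background(founders[[sf]], mutation_rate, prot_sites)
    coord <- seq_along(cs)  # final coordinate of each original position
    if (indel_rate > 0) {
      n_indel <- stats::rpois(1L, indel_rate)
      for (k in seq_len(n_indel)) {
        unprotected <- which(is.na(coord) | !(coord %in% prot_window))
        if (!length(unprotected)) break
        at <- sample(unprotected, 1L)
        if (stats::runif(1) < 0.5) {      # insertion of 1-3 residues
          ins <- sample(AA20, sample(1:3, 1L), replace = TRUE)
          cs <- append(cs, ins, after = at)
          coord <- append(coord, rep(NA_integer_, length(ins)), after = at)
        } else {                          # deletion of 1-3 residues
          del_len <- min(sample(1:3, 1L), length(cs) - at + 1L)
          del <- at + seq_len(del_len) - 1L
          if (any(!is.na(coord[del]) & coord[del] %in% prot_window)) next
          cs <- cs[-del]; coord <- coord[-del]
        }
      }
    }
    final_of <- function(p) which(coord == p)[1]
    records <- rbind(records, data.frame(
      record_id = id, subfamily = sf, sequence = paste(cs, collapse = ""),
      stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      record_id = id, site = site_names,
      residue = vapply(site_pos, function(p) cs[final_of(p)], ""),
      coordinate = vapply(site_pos, final_of, 1L), stringsAsFactors = FALSE))
  }
  list(records = records, founders = vapply(founders, paste, "", collapse = ""),
       truth = truth)
}

#' Generate a study-shaped curation candidate pool
#'
#' Builds a complete family census plus the redundancy the curation step
#' must remove: NPA-less transcript variants of one gene, an exact partial
#' duplicate of another, and upstream fragments carrying only the loop-E
#' motif. Mirrors the structure of a raw homology-search harvest.
#'
#' @param template_annotation A [load_template()] object.
#' @param subfamilies Subfamily label per true member (default: 12 PIP, 8
#'   TIP, 8 NIP, 2 SIP, 1 XIP, the census of the melon study).
#' @param n_variants,n_fragments,n_partials Counts of each artefact class.
#' @param seed Integer seed.
#' @return List: `records` (with `gene_name`), `expected_retained`,
#'   `expected_discarded` (data frame `record_id`, `reason`).
#' @export
generate_census_input <- function(template_annotation,
                                  subfamilies = c(rep("PIP1", 2), rep("PIP2", 10),
                                                  rep("TIP", 8), rep("NIP", 8),
                                                  rep("SIP", 2), "XIP"),
                                  n_variants = 2L, n_fragments = 3L,
                                  n_partials = 1L, seed = 1L) {
  fam <- generate_family(subfamilies, template_annotation, seed = seed)
  rec <- fam$records
  rec$gene_name <- rec$record_id
  pos <- template_annotation$positions
  set.seed(seed + 1000L)
  extra <- NULL
  # transcript variants of the first gene with both loop motifs destroyed
  for (k in seq_len(n_variants)) {
    cs <- chars(rec$sequence[1])
    for (p in c(pos[["npa_lb"]], pos[["npa_le"]])) cs[p + 1] <- "G"  # P -> G kills motif
    extra <- rbind(extra, data.frame(
      record_id = sprintf("%s_var%d", rec$record_id[1], k),
      subfamily = rec$subfamily[1], sequence = paste(cs, collapse = ""),
      gene_name = rec$gene_name[1], stringsAsFactors = FALSE))
  }
  # exact partial duplicates of the second gene (both motifs retained)
  for (k in seq_len(n_partials)) {
    s <- rec$sequence[2]
    extra <- rbind(extra, data.frame(
      record_id = sprintf("%s_part%d", rec$record_id[2], k),
      subfamily = rec$subfamily[2],
      sequence = substr(s, 15L, nchar(s) - 10L),
      gene_name = NA_character_, stringsAsFactors = FALSE))
  }
  # upstream fragments containing only the loop-E motif
  frag_src <- sample(3:nrow(rec), n_fragments)
  for (k in seq_len(n_fragments)) {
    s <- rec$sequence[frag_src[k]]
    extra <- rbind(extra, data.frame(
      record_id = sprintf("frag%02d", k), subfamily = NA_character_,
      sequence = substr(s, pos[["npa_lb"]] + 20L, nchar(s)),
      gene_name = NA_character_, stringsAsFactors = FALSE))
  }
  all_rec <- rbind(rec, extra)
  expected <- data.frame(
    record_id = extra$record_id,
    reason = c(rep("transcript_variant", n_variants),
               rep("partial_duplicate", n_partials),
               rep("missing_npa", n_fragments)),
    stringsAsFactors = FALSE)
  list(records = all_rec, expected_retained = rec$record_id,
       expected_discarded = expected)
}

#' Generate a Ct matrix with known relative abundances
#'
#' `Ct = ct0 - log_(1+E)(abundance) + N(0, noise_sd)` per technical
#' replicate; biological replicates draw a per-sample abundance jitter of
#' `bio_sd` on the log2 scale; cells above the detection ceiling become
#' `NA`. Reference genes are generated with their own stability sd.
#'
#' @param abundance Data frame `gene`, `tissue`, `abundance` (> 0, relative
#'   units) for the target genes.
#' @param ref_genes Character vector of reference gene names (abundance 1 in
#'   every tissue).
#' @param ref_sd Log2-scale biological stability sd of the reference genes
#'   (default 0.05).
#' @param n_bio,n_tech Biological / technical replicates per tissue
#'   (defaults 4 and 3; the study used 3-6 and 3).
#' @param efficiencies Named per-gene E (default 1 = perfect doubling).
#' @param noise_sd Technical noise sd in cycles (default 0.2).
#' @param bio_sd Biological log2 abundance jitter (default 0.1).
#' @param ct0 Ct of one abundance unit (default 24).
#' @param ceiling_ct Detection ceiling (default 38).
#' @param seed Integer seed.
#' @return List: `ct` (long data frame gene/sample/tissue/bio_rep/tech_rep/
#'   ct), `truth` (the input abundances plus the per-tissue fold changes).
#' @export
generate_ct <- function(abundance, ref_genes = "REF1", ref_sd = 0.05,
                        n_bio = 4L, n_tech = 3L, efficiencies = NULL,
                        noise_sd = 0.2, bio_sd = 0.1, ct0 = 24,
                        ceiling_ct = 38, seed = 1L) {
  stopifnot(all(c("gene", "tissue", "abundance") %in% names(abundance)),
            all(abundance$abundance > 0), noise_sd >= 0)
  set.seed(seed)
  tissues <- unique(abundance$tissue)
  genes <- unique(abundance$gene)
  rows <- NULL
  for (tis in tissues) for (b in seq_len(n_bio)) {
    sample_id <- sprintf("%s_b%d", tis, b)
    for (g in c(ref_genes, genes)) {
      is_ref <- g %in% ref_genes
      ab <- if (is_ref) 1 else
        abundance$abundance[abundance$gene == g & abundance$tissue == tis]
      if (!length(ab)) next
      e <- if (!is.null(efficiencies) && g %in% names(efficiencies))
        efficiencies[[g]] else 1
      jitter_sd <- if (is_ref) ref_sd else bio_sd
      ab_b <- ab * 2^stats::rnorm(1, 0, jitter_sd)
      mu <- ct0 - log(ab_b, base = 1 + e)
      ctv <- mu + stats::rnorm(n_tech, 0, noise_sd)
      ctv[ctv > ceiling_ct] <- NA_real_
      ctv[!is.na(ctv) & ctv <= 0] <- 0.01
      rows <- rbind(rows, data.frame(
        gene = g, sample = sample_id, tissue = tis, bio_rep = b,
        tech_rep = seq_len(n_tech), ct = ctv, stringsAsFactors = FALSE))
    }
  }
  truth <- abundance
  if (length(tissues) == 2L) {
    a1 <- abundance[abundance$tissue == tissues[1], ]
    a2 <- abundance[abundance$tissue == tissues[2], ]
    fc <- merge(a1, a2, by = "gene", suffixes = c("_1", "_2"))
    fc$fold_change <- fc$abundance_2 / fc$abundance_1
    attr(truth, "fold_change") <- fc[c("gene", "fold_change")]
  }
  list(ct = rows, truth = truth)
}

#' Generate paired qPCR / RNA-seq tables with known concordance classes
#'
#' Builds per-gene two-tissue profiles, then derives the second platform by
#' construction: `concordant` genes share the profile, `tissue_specific`
#' genes are shifted `discord_fold`-fold in one tissue, `discordant` genes
#' in both. The first two concordant genes are dominant "anchor" isoforms
#' (one tops each platform, the way one tonoplast and one plasma-membrane
#' isoform dominate the two real platforms), so each platform's max-100
#' rescaling anchor falls on a *different* gene yet the constructed classes
#' survive rescaling. Platform-specific raw scales also differ.
#'
#' @param n_concordant Class size (>= 2; includes the two anchors).
#' @param n_tissue_specific,n_discordant Class sizes.
#' @param tissues Two tissue labels.
#' @param discord_fold Fold shift used to build disagreement (default 10).
#' @param seed Integer seed.
#' @return List: `qpcr`, `rnaseq` (data frames gene/tissue/value), `truth`
#'   (gene/class).
#' @export
generate_platform_pair <- function(n_concordant = 6L, n_tissue_specific = 9L,
                                   n_discordant = 13L,
                                   tissues = c("root", "leaf"),
                                   discord_fold = 10, seed = 1L) {
  stopifnot(length(tissues) == 2L, n_concordant >= 2L)
  set.seed(seed)
  n <- n_concordant + n_tissue_specific + n_discordant
  genes <- sprintf("gene%02d", seq_len(n))
  classes <- rep(c("concordant", "tissue_specific", "discordant"),
                 c(n_concordant, n_tissue_specific, n_discordant))
  # bulk genes well below the anchors so a discord_fold boost cannot
  # overtake the rescaling anchors
  base <- matrix(2^stats::runif(2 * n, 1, 2.5), n, 2,
                 dimnames = list(genes, tissues))
  other <- base
  base[1, ] <- c(100, 95); other[1, ] <- c(80, 76)    # platform-1 top
  base[2, ] <- c(80, 76); other[2, ] <- c(100, 95)    # platform-2 top
  for (i in seq_len(n)) {
    if (classes[i] == "tissue_specific") {
      t_shift <- sample(1:2, 1L)
      other[i, t_shift] <- other[i, t_shift] *
        discord_fold^(sample(c(-1, 1), 1L))
    } else if (classes[i] == "discordant") {
      other[i, ] <- other[i, ] * discord_fold^(sample(c(-1, 1), 2L, replace = TRUE))
    }
  }
  long <- function(m, scale) data.frame(
    gene = rep(rownames(m), 2L), tissue = rep(colnames(m), each = nrow(m)),
    value = c(m[, 1], m[, 2]) * scale, stringsAsFactors = FALSE)
  list(qpcr = long(base, 1), rnaseq = long(other, 7.3),
       truth = data.frame(gene = genes, class = classes,
                          stringsAsFactors = FALSE))
}
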