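# Nearest-neighbour DNA thermodynamics for primer QC.
#
# Two published parameter sets are shipped:
#   * santalucia1998 - the unified dH/dS table (1 M NaCl baseline), the
#     de-facto standard; used for dimer/hairpin screening and Tm. Duplex
#     dG includes initiation and terminal-AT penalties, plus the entropic
#     salt correction when conditions deviate from 1 M monovalent.
#   * breslauer1986 - the older stack table evaluated at 25 C without an
#     initiation term, i.e. the "total dG" printed by the classic primer
#     screening web tools; reproduces the study's full-primer dG column.

# dH kcal/mol, dS cal/(mol K); keys are the 5'->3' top-strand dinucleotides
NN_SL98_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
                CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_SL98_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
                CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
SL98_INIT_GC <- c(dh = 0.1, ds = -2.8)   # per terminal G.C pair
SL98_INIT_AT <- c(dh = 2.3, ds = 4.1)    # per terminal A.T pair
SL98_SYM_DS <- -1.4                       # self-complementary correction

NN_BR86_DH <- c(AA = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, GT = -6.5,
                CT = -7.8, GA = -5.6, CG = -11.9, GC = -11.1, GG = -11.0)
NN_BR86_DS <- c(AA = -24.0, AT = -23.9, TA = -16.9, CA = -12.9, GT = -17.3,
                CT = -20.8, GA = -13.5, CG = -27.8, GC = -26.7, GG = -26.6)

# hairpin loop penalties dG37 (kcal/mol) by loop length; Jacobson-Stockmayer
# extrapolation beyond the table
HAIRPIN_LOOP_DG <- c(`3` = 3.5, `4` = 3.5, `5` = 3.3, `6` = 4.0, `7` = 4.1,
                     `8` = 4.3, `9` = 4.5, `10` = 4.9)

#' Reaction conditions for thermodynamic calculations
#'
#' @param temperature_c Evaluation temperature for free energies (deg C).
#' @param monovalent_mM Monovalent cation concentration; the nearest-
#'   neighbour tables are parameterized at 1000 mM (1 M NaCl) and an
#'   entropic salt correction (0.368 cal/K per stack per ln M) is applied
#'   when it deviates.
#' @param oligo_uM Total strand concentration used for Tm.
#' @return List of class `thermo_conditions`.
#' @export
thermo_conditions <- function(temperature_c = 37, monovalent_mM = 1000,
                              oligo_uM = 0.25) {
  stopifnot(monovalent_mM > 0, oligo_uM > 0)
  structure(list(temperature_c = temperature_c, monovalent_mM = monovalent_mM,
                 oligo_uM = oligo_uM), class = "thermo_conditions")
}

#' Reverse complement of a DNA strand
#'
#' @param strand DNA string, 5'->3'.
#' @return Reverse complement, 5'->3'.
#' @export
revcomp <- function(strand) {
  validate_dna(strand)
  paste(rev(chars(chartr("ACGT", "TGCA", toupper(strand)))), collapse = "")
}

nn_tables <- function(params) {
  switch(params,
         santalucia1998 = list(dh = NN_SL98_DH, ds = NN_SL98_DS, init = TRUE,
                               default_temp = 37),
         breslauer1986 = list(dh = NN_BR86_DH, ds = NN_BR86_DS, init = FALSE,
                              default_temp = 25),
         stop("unknown parameter set: ", params))
}

stack_key <- function(dinuc) {
  # dG(XY) = dG(revcomp(XY)); table stores one orientation
  rc <- vapply(dinuc, function(d)
    paste(rev(chars(chartr("ACGT", "TGCA", d))), collapse = ""), "")
  ifelse(dinuc %in% names(NN_SL98_DH), dinuc, rc)
}

# dH/dS sums over the stacks of a contiguous duplex given by its top strand
duplex_hs <- function(top, tab, with_init) {
  cs <- chars(top)
  din <- paste0(cs[-length(cs)], cs[-1])
  keys <- stack_key(din)
  dh <- sum(tab$dh[keys]); ds <- sum(tab$ds[keys])
  if (with_init) {
    for (term in c(cs[1], cs[length(cs)])) {
      add <- if (term %in% c("G", "C")) SL98_INIT_GC else SL98_INIT_AT
      dh <- dh + add[["dh"]]; ds <- ds + add[["ds"]]
    }
  }
  c(dh = dh, ds = ds, nstacks = length(din))
}

dg_from_hs <- function(hs, conditions, symmetry = FALSE) {
  tk <- conditions$temperature_c + 273.15
  ds <- hs[["ds"]] + 0.368 * hs[["nstacks"]] * log(conditions$monovalent_mM / 1000)
  if (symmetry) ds <- ds + SL98_SYM_DS
  hs[["dh"]] - tk * ds / 1000
}

#' Free energy of a full-length perfect duplex
#'
#' Nearest-neighbour stack sum for `strand_a` hybridized antiparallel to its
#' exact reverse complement, with initiation and terminal-pair terms for the
#' `santalucia1998` set (the `breslauer1986` set reports the bare stack sum
#' at 25 C, as the classic screening tools do).
#'
#' @param strand_a DNA string, 5'->3'.
#' @param strand_b Its hybridization partner; must equal `revcomp(strand_a)`
#'   (mismatched duplexes are out of scope; see [best_dimer_dg()]).
#' @param conditions A [thermo_conditions()] object; `NULL` uses the
#'   parameter set's published baseline.
#' @param params `"santalucia1998"` (default) or `"breslauer1986"`.
#' @return Free energy in kcal/mol.
#' @export
duplex_dg <- function(strand_a, strand_b = revcomp(strand_a),
                      conditions = NULL, params = "santalucia1998") {
  a <- validate_dna(strand_a, "strand_a")
  b <- validate_dna(strand_b, "strand_b")
  if (b != revcomp(a))
    stop("strand_b must be the exact reverse complement of strand_a")
  tab <- nn_tables(params)
  if (is.null(conditions))
    conditions <- thermo_conditions(temperature_c = tab$default_temp)
  hs <- duplex_hs(a, tab, with_init = tab$init)
  dg_from_hs(hs, conditions, symmetry = tab$init && a == revcomp(a))
}

complementary <- function(x, y) {
  (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "C" & y == "G") | (x == "G" & y == "C")
}

#' Strongest ungapped dimer between two strands
#'
#' Slides the two strands against each other antiparallel (offsets only, no
#' internal loops), scores every maximal run of >= 2 consecutive
#' complementary pairs as a short duplex (stacks + initiation), and returns
#' the most negative free energy. Mismatched flanks are ignored.
#'
#' @param strand_a,strand_b DNA strings, 5'->3' (`strand_b = strand_a` for a
#'   self-dimer).
#' @param conditions A [thermo_conditions()] object (default 37 C, 1 M).
#' @return Minimum dG in kcal/mol, or `NA` when no offset has two
#'   consecutive complementary pairs.
#' @export
best_dimer_dg <- function(strand_a, strand_b = strand_a, conditions = NULL) {
  a <- chars(validate_dna(strand_a, "strand_a"))
  bb <- chars(validate_dna(strand_b, "strand_b"))
  if (is.null(conditions)) conditions <- thermo_conditions()
  tab <- nn_tables("santalucia1998")
  b <- rev(bb)  # antiparallel: pair a[i] with b3'->5'
  na <- length(a); nb <- length(b)
  best <- NA_real_
  for (s in (-(nb - 1)):(na - 1)) {
    i <- max(1L, 1L + s):min(na, nb + s)
    j <- i - s
    comp <- complementary(a[i], b[j])
    if (!any(comp)) next
    runs <- rle(comp)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values & runs$lengths >= 2L)) {
      top <- paste(a[i[starts[k]:ends[k]]], collapse = "")
      dg <- dg_from_hs(duplex_hs(top, tab, with_init = TRUE), conditions,
                       symmetry = top == revcomp(top))
      if (is.na(best) || dg < best) best <- dg
    }
  }
  best
}

#' Strongest hairpin of a strand
#'
#' Enumerates all stem-loop decompositions with stem >= 3 bp and loop >= 3
#' nt; the free energy is the stem's stack sum plus a loop-length penalty
#' (tabulated to loop 10, Jacobson-Stockmayer extrapolation beyond).
#' Orientation-dependent: `hairpin_dg(s)` generally differs from
#' `hairpin_dg(reverse(s))`.
#'
#' @param strand DNA string, 5'->3'.
#' @param conditions A [thermo_conditions()] object (default 37 C, 1 M).
#' @param min_stem,min_loop Structural bounds.
#' @return Minimum dG in kcal/mol, or `NA` when no stem-loop is possible.
#' @export
hairpin_dg <- function(strand, conditions = NULL, min_stem = 3L, min_loop = 3L) {
  s <- chars(validate_dna(strand))
  if (is.null(conditions)) conditions <- thermo_conditions()
  tab <- nn_tables("santalucia1998")
  n <- length(s)
  best <- NA_real_
  tk <- conditions$temperature_c + 273.15
  loop_pen <- function(L) {
    if (L <= 10) HAIRPIN_LOOP_DG[[as.character(max(L, 3L))]]
    else HAIRPIN_LOOP_DG[["10"]] + 1.75 * 0.0019872 * tk * log(L / 10)
  }
  for (i in seq_len(n)) for (j in n:(i + 2 * min_stem + min_loop - 1)) {
    if (j > n || j - i + 1 < 2 * min_stem + min_loop) next
    k <- 0L
    while (i + k < j - k && complementary(s[i + k], s[j - k])) k <- k + 1L
    if (k < min_stem) next
    for (stem in min_stem:k) {
      loop <- (j - stem) - (i + stem) + 1L
      if (loop < min_loop) next
      top <- paste(s[i:(i + stem - 1L)], collapse = "")
      hs <- duplex_hs(top, tab, with_init = FALSE)
      dg <- dg_from_hs(hs, conditions) + loop_pen(loop)
      if (is.na(best) || dg < best) best <- dg
    }
  }
  best
}

#' Nearest-neighbour melting temperature
#'
#' Two-state Tm from the unified dH/dS sums (initiation included) with the
#' entropic salt correction: `Tm = dH / (dS + R ln(C_T/4)) - 273.15`.
#'
#' @param strand DNA string, 5'->3'.
#' @param conditions A [thermo_conditions()] object.
#' @return Tm in deg C.
#' @export
tm_nn <- function(strand, conditions = thermo_conditions(monovalent_mM = 50)) {
  a <- validate_dna(strand)
  hs <- duplex_hs(a, nn_tables("santalucia1998"), with_init = TRUE)
  ds <- hs[["ds"]] + 0.368 * hs[["nstacks"]] * log(conditions$monovalent_mM / 1000)
  if (a == revcomp(a)) ds <- ds + SL98_SYM_DS
  ct <- conditions$oligo_uM * 1e-6
  hs[["dh"]] * 1000 / (ds + 1.987 * log(ct / 4)) - 273.15
}

#' Screen a primer pair
#'
#' Applies the dimer acceptance rule (every self- and hetero-dimer dG must be
#' *less stable* than the threshold, i.e. `dG > -6.5` kcal/mol by default),
#' a hairpin threshold, and length/GC bounds. All reasons are enumerated on
#' failure.
#'
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param conditions A [thermo_conditions()] object (default 37 C, 1 M).
#' @param dimer_threshold Dimer dG floor in kcal/mol (default -6.5).
#' @param hairpin_threshold Hairpin dG floor (default -3).
#' @param length_range,gc_range Acceptable primer length and GC fraction.
#' @return List of class `thermo_report`: the dG panel (`dg_primer_f/r`,
#'   `dg_self_f/r`, `dg_hetero`, `dg_hairpin_f/r`), `tm_f`, `tm_r`, `pass`,
#'   `failed_checks`.
#' @export
screen_pair <- function(forward, reverse, conditions = NULL,
                        dimer_threshold = -6.5, hairpin_threshold = -3,
                        length_range = c(15L, 30L), gc_range = c(0.2, 0.8)) {
  f <- validate_dna(forward, "forward")
  r <- validate_dna(reverse, "reverse")
  if (is.null(conditions)) conditions <- thermo_conditions()
  gc <- function(s) mean(chars(s) %in% c("G", "C"))
  rep_ <- list(
    dg_primer_f = duplex_dg(f, conditions = conditions),
    dg_primer_r = duplex_dg(r, conditions = conditions),
    dg_self_f = best_dimer_dg(f, f, conditions),
    dg_self_r = best_dimer_dg(r, r, conditions),
    dg_hetero = best_dimer_dg(f, r, conditions),
    dg_hairpin_f = hairpin_dg(f, conditions),
    dg_hairpin_r = hairpin_dg(r, conditions),
    tm_f = tm_nn(f), tm_r = tm_nn(r))
  failed <- character()
  chk_dimer <- function(val, what) {
    if (!is.na(val) && val <= dimer_threshold)
      failed <<- c(failed, sprintf("%s dG %.2f <= %.2f kcal/mol", what, val,
                                   dimer_threshold))
  }
  chk_dimer(rep_$dg_self_f, "forward self-dimer")
  chk_dimer(rep_$dg_self_r, "reverse self-dimer")
  chk_dimer(rep_$dg_hetero, "hetero-dimer")
  for (nm in c("f", "r")) {
    hp <- rep_[[paste0("dg_hairpin_", nm)]]
    if (!is.na(hp) && hp <= hairpin_threshold)
      failed <- c(failed, sprintf("%s hairpin dG %.2f <= %.2f kcal/mol",
                                  if (nm == "f") "forward" else "reverse", hp,
                                  hairpin_threshold))
    s <- if (nm == "f") f else r
    if (nchar(s) < length_range[1] || nchar(s) > length_range[2])
      failed <- c(failed, sprintf("%s length %d outside [%d, %d]",
                                  if (nm == "f") "forward" else "reverse",
                                  nchar(s), length_range[1], length_range[2]))
    if (gc(s) < gc_range[1] || gc(s) > gc_range[2])
      failed <- c(failed, sprintf("%s GC %.2f outside [%.2f, %.2f]",
                                  if (nm == "f") "forward" else "reverse",
                                  gc(s), gc_range[1], gc_range[2]))
  }
  structure(c(rep_, list(pass = !length(failed), failed_checks = failed)),
            class = "thermo_report")
}
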