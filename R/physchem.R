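# Protein physico-chemical properties: isoelectric point by bisection on the
# Henderson-Hasselbalch net charge (Bjellqvist pKa set, as used by the common
# web calculators) and average molecular mass.

# Bjellqvist pKa values: side chains, default termini, and the
# first-residue-dependent N-terminal exceptions.
PKA_SIDE <- c(C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0, R = 12.0, Y = 10.0)
PKA_NTERM_DEFAULT <- 7.5
PKA_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7, G = 7.5)
PKA_CTERM_DEFAULT <- 3.55
PKA_CTERM <- c(D = 4.55, E = 4.75)

# IUPAC average residue masses (Da); water added once per chain
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
             E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
             L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
             S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable side chains (C, D, E, H, K,
#' R, Y) and both termini, with the Bjellqvist pKa set. Monotone decreasing
#' in pH.
#'
#' @param sequence Amino-acid string (20-letter alphabet; `X` allowed with
#'   `allow_x = TRUE`, contributing no ionizable group).
#' @param ph pH value(s).
#' @param allow_x Tolerate `X` residues.
#' @return Net charge (elementary charges), vectorized over `ph`.
#' @export
net_charge <- function(sequence, ph, allow_x = FALSE) {
  validate_protein(sequence, allow_x = allow_x)
  cs <- chars(sequence)
  counts <- table(factor(cs, levels = c(AA20, "X")))
  first <- cs[1]; last <- cs[length(cs)]
  pk_n <- if (first %in% names(PKA_NTERM)) PKA_NTERM[[first]] else PKA_NTERM_DEFAULT
  pk_c <- if (last %in% names(PKA_CTERM)) PKA_CTERM[[last]] else PKA_CTERM_DEFAULT
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))
  neg_frac <- function(pk) 1 / (1 + 10^(pk - ph))
  pos <- pos_frac(pk_n) +
    counts[["K"]] * pos_frac(PKA_SIDE[["K"]]) +
    counts[["R"]] * pos_frac(PKA_SIDE[["R"]]) +
    counts[["H"]] * pos_frac(PKA_SIDE[["H"]])
  neg <- neg_frac(pk_c) +
    counts[["D"]] * neg_frac(PKA_SIDE[["D"]]) +
    counts[["E"]] * neg_frac(PKA_SIDE[["E"]]) +
    counts[["C"]] * neg_frac(PKA_SIDE[["C"]]) +
    counts[["Y"]] * neg_frac(PKA_SIDE[["Y"]])
  pos - neg
}

#' Isoelectric point
#'
#' Solves `net_charge(pH) = 0` by bisection on `[0, 14]` to a residual
#' `|charge| < 1e-4`. The charge function is strictly decreasing in pH (the
#' termini are always ionizable), so the root is unique.
#'
#' @inheritParams net_charge
#' @return pI (pH units).
#' @export
#' @examples
#' compute_pi("GG")  # midpoint of the two terminal pKa values
compute_pi <- function(sequence, allow_x = FALSE) {
  validate_protein(sequence, allow_x = allow_x)
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, allow_x = allow_x)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Average molecular mass
#'
#' Sum of IUPAC average residue masses plus one water, in kDa. `X` residues
#' are an error unless `allow_x = TRUE`, in which case each contributes the
#' mean residue mass of the 20 standard amino acids.
#'
#' @inheritParams net_charge
#' @return Mass in kDa (full precision; round at display time).
#' @export
#' @examples
#' compute_mw("G")  # glycine residue + water = 0.0750672 kDa
compute_mw <- function(sequence, allow_x = FALSE) {
  validate_protein(sequence, allow_x = TRUE)
  cs <- chars(sequence)
  if (!allow_x && any(cs == "X"))
    stop("sequence contains X; set allow_x = TRUE to substitute the mean residue mass")
  masses <- c(AA_MASS, X = mean(AA_MASS))
  (sum(masses[cs]) + WATER_MASS) / 1000
}
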