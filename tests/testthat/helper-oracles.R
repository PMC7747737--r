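# Independent nearest-neighbour oracle: constants transcribed separately
# from the implementation (unified dH kcal/mol, dS cal/mol/K) and a direct
# pair-by-pair enumeration of antiparallel ungapped dimers.

NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)

nn_dg37 <- function(dinuc) {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", dinuc), "")[[1]]),
              collapse = "")
  key <- if (dinuc %in% names(NN_DH)) dinuc else rc
  NN_DH[[key]] - 310.15 * NN_DS[[key]] / 1000
}

init_dg37 <- function(base) {
  if (base %in% c("G", "C")) 0.1 - 310.15 * (-2.8) / 1000
  else 2.3 - 310.15 * 4.1 / 1000
}

oracle_dimer <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- rev(strsplit(b, "")[[1]])
  comp <- function(x, y) (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  best <- NA_real_
  for (s in (-(length(B) - 1)):(length(A) - 1)) {
    idx <- max(1, 1 + s):min(length(A), length(B) + s)
    cc <- comp(A[idx], B[idx - s])
    r <- rle(cc); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= 2)) {
      run <- A[idx[starts[k]:ends[k]]]
      dg <- sum(vapply(paste0(run[-length(run)], run[-1]), nn_dg37, 1.0)) +
        init_dg37(run[1]) + init_dg37(run[length(run)])
      rc_run <- paste(rev(chartr("ACGT", "TGCA", run)), collapse = "")
      if (paste(run, collapse = "") == rc_run)
        dg <- dg - 310.15 * (-1.4) / 1000
      if (is.na(best) || dg < best) best <- dg
    }
  }
  best
}
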