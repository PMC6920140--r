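# Independent oracles used across the suite. Constants here are typed from
# standard reference tables, deliberately not read from the package.

# Residue monoisotopic masses (ExPASy/Unimod table, 5 decimals).
ORACLE_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_WATER <- 18.01056
ORACLE_PROTON <- 1.00728
ORACLE_H <- 1.00783

# Residue elemental formulas (typed independently, CHNOS order strings).
ORACLE_RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1), L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1), N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3), Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1), E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1), H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1), R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2), W = c(C = 11, H = 10, N = 2, O = 1)
)

# Brute-force residue summation: formula of a peptide with n_disulfides
# bridges, as a named count vector (no package code involved).
oracle_peptide_formula <- function(sequence, n_disulfides = 0) {
  letters <- strsplit(sequence, "")[[1]]
  tot <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (a in letters) {
    f <- ORACLE_RESIDUE_FORMULA[[a]]
    tot[names(f)] <- tot[names(f)] + f
  }
  tot["H"] <- tot["H"] + 2 - 2 * n_disulfides
  tot["O"] <- tot["O"] + 1
  tot[tot > 0]
}

# Isotope table for the enumeration oracle, with explicit nucleon offsets
# (note sulfur's missing 35S: offsets 0, 1, 2, 4).
ORACLE_ISOTOPES <- list(
  H = data.frame(off = 0:1, mass = c(1.007825032, 2.014101778),
                 p = c(0.999885, 0.000115)),
  C = data.frame(off = 0:1, mass = c(12, 13.003354835),
                 p = c(0.9893, 0.0107)),
  N = data.frame(off = 0:1, mass = c(14.003074005, 15.000108899),
                 p = c(0.99636, 0.00364)),
  O = data.frame(off = 0:2, mass = c(15.994914620, 16.999131757, 17.999159613),
                 p = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(off = c(0, 1, 2, 4),
                 mass = c(31.972071, 32.971458759, 33.967866902, 35.96708076),
                 p = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# Full enumeration over every atom's isotope choice (feasible <= ~12 atoms),
# aggregated per nucleon offset with abundance-weighted centroid masses.
oracle_isotope_pattern <- function(counts, n_keep = 8) {
  atoms <- rep(names(counts), counts)
  choices <- lapply(atoms, function(el) seq_len(nrow(ORACLE_ISOTOPES[[el]])))
  grid <- as.matrix(expand.grid(choices))
  mass <- matrix(0, nrow(grid), length(atoms))
  prob <- matrix(0, nrow(grid), length(atoms))
  off <- matrix(0L, nrow(grid), length(atoms))
  for (j in seq_along(atoms)) {
    tab <- ORACLE_ISOTOPES[[atoms[j]]]
    mass[, j] <- tab$mass[grid[, j]]
    prob[, j] <- tab$p[grid[, j]]
    off[, j] <- tab$off[grid[, j]]
  }
  m <- rowSums(mass)
  p <- apply(prob, 1, prod)
  o <- rowSums(off)
  ab <- tapply(p, o, sum)
  cm <- tapply(p * m, o, sum) / ab
  out <- data.frame(offset = as.integer(names(ab)),
                    mass = as.numeric(cm), abundance = as.numeric(ab))
  out <- out[order(out$offset), ][seq_len(min(n_keep, nrow(out))), ]
  rownames(out) <- NULL
  out
}

# Independent full-enumeration Friedman p-value for untied data: iterates
# every assignment of rank permutations to subjects and uses the classic
# closed-form statistic Q = 12/(n k (k+1)) * sum Rj^2 - 3 n (k+1).
oracle_friedman_exact <- function(blocks) {
  n <- nrow(blocks)
  k <- ncol(blocks)
  classic_q <- function(rk) {
    rj <- colSums(rk)
    12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  }
  obs <- classic_q(t(apply(blocks, 1, rank)))
  perms <- as.matrix(expand.grid(rep(list(1:k), k)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == k), , drop = FALSE]
  combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
  stats_all <- apply(combos, 1, function(ix) {
    classic_q(perms[ix, , drop = FALSE])
  })
  list(statistic = obs, p = mean(stats_all >= obs - 1e-12))
}

# Small shared fixtures.
HEP_SEQ <- "DTHFPICIFCCGCCKTPKCGFCCRT"
REC_SEQ <- "DTHFPICIFCCGCCKTPKCGLCCKT"
OBSERVED_MZ <- data.frame(mz = c(556.420376, 695.273485, 926.695333),
                          z = c(5, 4, 3))
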