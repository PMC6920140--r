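#' Align LC-MS features across samples
#'
#' Greedy centroid clustering of per-sample peak lists: peaks are visited
#' in decreasing area and joined to the first existing feature whose
#' running centroid lies within both the retention-time and the mass
#' tolerance; otherwise they seed a new feature. Defaults follow common
#' TOF-MS alignment settings (0.10 min, 0.05 Da).
#'
#' @param tables Named list of per-sample data frames with columns `mz`,
#'   `rt` (minutes) and `area`.
#' @param rt_tol Retention-time tolerance in minutes (default 0.10).
#' @param mz_tol Mass tolerance in Da (default 0.05).
#' @return Long-format data frame with columns `sample`, `feature`, `mz`,
#'   `rt`, `area`; one feature id per cluster.
#' @export
align_features <- function(tables, rt_tol = 0.10, mz_tol = 0.05) {
  if (length(tables) < 1) stop("need at least one sample table")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("sample", seq_along(tables))
  }
  pooled <- do.call(rbind, lapply(names(tables), function(s) {
    t <- as.data.frame(tables[[s]])
    if (!all(c("mz", "rt", "area") %in% names(t))) {
      stop("sample table '", s, "' needs mz, rt, area columns")
    }
    if (any(t$area < 0)) stop("areas must be >= 0")
    data.frame(sample = s, mz = t$mz, rt = t$rt, area = t$area)
  }))
  ord <- order(-pooled$area)
  cent_mz <- numeric(0)
  cent_rt <- numeric(0)
  cent_n <- integer(0)
  feature <- integer(nrow(pooled))
  for (i in ord) {
    hit <- which(abs(cent_mz - pooled$mz[i]) <= mz_tol &
                 abs(cent_rt - pooled$rt[i]) <= rt_tol)
    if (length(hit) >= 1) {
      f <- hit[1]
      cent_mz[f] <- (cent_mz[f] * cent_n[f] + pooled$mz[i]) / (cent_n[f] + 1)
      cent_rt[f] <- (cent_rt[f] * cent_n[f] + pooled$rt[i]) / (cent_n[f] + 1)
      cent_n[f] <- cent_n[f] + 1L
    } else {
      cent_mz <- c(cent_mz, pooled$mz[i])
      cent_rt <- c(cent_rt, pooled$rt[i])
      cent_n <- c(cent_n, 1L)
      f <- length(cent_mz)
    }
    feature[i] <- f
  }
  pooled$feature <- paste0("F", sprintf("%03d", feature))
  pooled[order(pooled$feature, pooled$sample),
         c("sample", "feature", "mz", "rt", "area")]
}

#' Percent relative standard deviation
#'
#' `sd(values) / mean(values) * 100` (sample standard deviation). The
#' standard reproducibility measure for internal-standard peak areas.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return \%RSD as a single number.
#' @export
#' @examples
#' percent_rsd(c(1, 2, 3))  # 50
percent_rsd <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; %RSD undefined")
  stats::sd(values) / m * 100
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of instrument response on concentration.
#'
#' @param concentrations Known concentrations (nM), >= 2 distinct values.
#' @param responses Instrument responses (e.g. internal-standard-normalized
#'   area ratios), same length.
#' @return A list of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `range` (min/max concentration), `n_points`.
#' @export
#' @examples
#' fit_calibration(1:8, 2 * (1:8) + 1)
fit_calibration <- function(concentrations, responses) {
  if (length(concentrations) != length(responses)) stop("length mismatch")
  if (length(concentrations) < 2) stop("need at least 2 calibration points")
  if (length(unique(concentrations)) < 2) {
    stop("all concentrations identical; cannot fit")
  }
  fit <- stats::lm(responses ~ concentrations)
  co <- stats::coef(fit)
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]), r_squared = r2,
         range = c(min(concentrations), max(concentrations)),
         n_points = length(concentrations)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration curve> response = ", signif(x$slope, 6), " * conc + ",
      signif(x$intercept, 6), "  (r2 = ", sprintf("%.4f", x$r_squared),
      ", ", x$n_points, " points, ", x$range[1], "-", x$range[2], " nM)\n",
      sep = "")
  invisible(x)
}

#' Quantify a response against a calibration curve
#'
#' Inverts the fitted line: `(response - intercept) / slope`. Responses
#' falling outside the calibrated concentration range are flagged.
#'
#' @param curve A [fit_calibration()] result.
#' @param response Numeric response value(s).
#' @return Data frame with columns `response`, `concentration` (nM),
#'   `in_range`.
#' @export
quantify <- function(curve, response) {
  if (!inherits(curve, "calibration_curve")) stop("need a calibration_curve")
  if (!is.finite(curve$slope) || abs(curve$slope) < 1e-12) {
    stop("zero slope; cannot invert calibration")
  }
  conc <- (response - curve$intercept) / curve$slope
  data.frame(response = response, concentration = conc,
             in_range = conc >= curve$range[1] & conc <= curve$range[2])
}

# Tie-corrected Friedman chi-square from a matrix of within-row mid-ranks.
.friedman_stat <- function(ranks) {
  n <- nrow(ranks)
  k <- ncol(ranks)
  col_sums <- colSums(ranks)
  num <- (k - 1) * sum((col_sums - n * (k + 1) / 2)^2)
  den <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) return(0)  # all rows constant
  num / den
}

#' Friedman rank test for complete repeated-measures blocks
#'
#' Nonparametric test for treatment (timepoint) differences across
#' complete blocks (subjects). Values are ranked within each subject with
#' mid-ranks for ties; the tie-corrected chi-square statistic
#' `Q = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (sum_ij r_ij^2 - nk(k+1)^2/4)`
#' is referred to a chi-square distribution with `k - 1` degrees of
#' freedom. With `exact = TRUE` the p-value is instead computed by full
#' enumeration of all `(k!)^n` within-subject rank permutations (feasible
#' for about `n <= 6`, `k <= 4`), conditioning on the observed tie
#' pattern of each row.
#'
#' @param blocks Numeric matrix, subjects in rows, treatments/timepoints
#'   in columns; no missing values (complete blocks required; rows with
#'   `NA` must be removed by the caller - listwise behavior is not
#'   applied silently).
#' @param exact Use exact permutation enumeration instead of the
#'   chi-square approximation (default `FALSE`).
#' @return A list of class `friedman_result`: `statistic`, `p_value`,
#'   `df`, `method`, `n`, `k`.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 3, 4, 1, 3, 5), nrow = 3, byrow = TRUE)
#' friedman_test(m)
friedman_test <- function(blocks, exact = FALSE) {
  blocks <- as.matrix(blocks)
  if (anyNA(blocks)) stop("incomplete blocks: remove rows with missing values first")
  n <- nrow(blocks)
  k <- ncol(blocks)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 timepoints")
  ranks <- t(apply(blocks, 1, rank))
  stat <- .friedman_stat(ranks)
  if (!exact) {
    p <- if (stat == 0 && all(apply(blocks, 1, function(r) length(unique(r)) == 1))) {
      1
    } else {
      stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    }
    method <- "chi-square approximation"
  } else {
    if (factorial(k)^n > 5e6) stop("exact enumeration infeasible for this size")
    perms <- .permutations(k)
    # all assignments of a permutation to each subject's observed mid-ranks
    # (all k! kept, so tied rank rows retain their permutation multiplicity)
    per_subject <- lapply(seq_len(n), function(i) {
      t(apply(perms, 1, function(p) ranks[i, p]))
    })
    idx <- lapply(per_subject, function(m) seq_len(nrow(m)))
    grid <- as.matrix(expand.grid(idx))
    stats_all <- apply(grid, 1, function(g) {
      r <- do.call(rbind, lapply(seq_len(n), function(i) per_subject[[i]][g[i], ]))
      .friedman_stat(r)
    })
    p <- mean(stats_all >= stat - 1e-12)
    method <- "exact permutation enumeration"
  }
  structure(list(statistic = stat, p_value = p, df = k - 1,
                 method = method, n = n, k = k),
            class = "friedman_result")
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' @export
print.friedman_result <- function(x, ...) {
  cat("Friedman test (", x$method, ")\n",
      "  Q = ", sprintf("%.4f", x$statistic), ", df = ", x$df,
      ", p = ", sprintf("%.4g", x$p_value),
      "  (n = ", x$n, " subjects, k = ", x$k, " timepoints)\n", sep = "")
  invisible(x)
}

#' Summarise a time-course and test for change over time
#'
#' Computes per-timepoint medians and quartiles and the Friedman test for
#' within-subject change over time.
#'
#' @param blocks Subjects x timepoints matrix of concentrations.
#' @param timepoints Numeric labels for columns (hours); defaults to
#'   column names or index.
#' @param exact Passed to [friedman_test()].
#' @return A list of class `timecourse_result`: `timepoints`, `summary`
#'   (data frame with median, q1, q3), `friedman` (a `friedman_result`).
#' @export
timecourse_test <- function(blocks, timepoints = NULL, exact = FALSE) {
  blocks <- as.matrix(blocks)
  if (is.null(timepoints)) {
    timepoints <- if (!is.null(colnames(blocks))) {
      suppressWarnings(as.numeric(colnames(blocks)))
    } else NULL
    if (is.null(timepoints) || anyNA(timepoints)) {
      timepoints <- seq_len(ncol(blocks)) - 1
    }
  }
  qs <- apply(blocks, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
  structure(
    list(timepoints = timepoints,
         summary = data.frame(timepoint = timepoints,
                              median = qs[2, ], q1 = qs[1, ], q3 = qs[3, ],
                              row.names = NULL),
         friedman = friedman_test(blocks, exact = exact)),
    class = "timecourse_result"
  )
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat("<time-course>\n")
  print(round(x$summary, 3))
  print(x$friedman)
  invisible(x)
}
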