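#' @include electivity.R
NULL

.testResult <- function(name, label, statistic, n, p, adjustment = "none") {
  data.frame(test = name, statistic_label = label,
             statistic = unname(statistic), n = n,
             p_value = unname(p), adjustment = adjustment,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mann-Whitney U (rank-sum) test
#'
#' Two-sample rank-sum comparison, used to compare the group's observed
#' percentage use of a feature against its expected (availability-based)
#' use.  Exact p-values are used for small untied samples, otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b numeric samples.
#' @param exact logical or NULL (NULL = exact when both n < 50 and no ties,
#'   the stats default).
#' @return one-row data.frame (test, statistic_label "W", statistic, n,
#'   p_value, adjustment).
#' @export
mannWhitneyTest <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  if (stats::var(c(a, b)) == 0)
    stop("all observations tied across both samples: rank test degenerate")
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  .testResult("mann_whitney", "W", wt$statistic,
              paste(length(a), length(b), sep = "+"), wt$p.value)
}

#' Wilcoxon signed-rank test
#'
#' One-sample signed-rank test on paired differences (e.g. warm-season
#' minus cold-season electivity per individual).  Zero differences are
#' dropped; exact p for small untied samples, otherwise the tie-corrected
#' normal approximation with the ±0.5 continuity correction when
#' `continuity` is TRUE.
#'
#' @param diffs numeric paired differences.
#' @param continuity apply the continuity correction on the normal path.
#' @param exact logical or NULL (stats default rule).
#' @return one-row data.frame with statistic_label "V".
#' @export
wilcoxonSignedRankTest <- function(diffs, continuity = TRUE, exact = NULL) {
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) stop("all differences are zero: test degenerate")
  wt <- suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = continuity))
  .testResult("wilcoxon_signed_rank", "V", wt$statistic, length(nz),
              wt$p.value)
}

#' Friedman rank test
#'
#' Nonparametric repeated-measures comparison across k conditions in b
#' blocks (e.g. per-feature electivity at morning / midday / afternoon for
#' each individual).  The tie-corrected chi-squared statistic follows
#' [stats::friedman.test()]; the p-value comes from the chi-squared
#' approximation or, when `exact = TRUE` and the design is small enough
#' ((k!)^b enumerable), from exhaustive within-block permutation.
#'
#' @param mat numeric matrix, blocks x conditions, no missing cells.
#' @param exact use the exact permutation null (limit `maxPerms`).
#' @param maxPerms cap on (k!)^b for the exact path; default 1e6.
#' @return one-row data.frame with statistic_label "chi_squared" plus a
#'   `df` column.
#' @export
friedmanRankTest <- function(mat, exact = FALSE, maxPerms = 1e6) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells are not supported (no imputation)")
  b <- nrow(mat); k <- ncol(mat)
  if (b < 2 || k < 2) stop("need at least 2 blocks and 2 conditions")
  ft <- stats::friedman.test(mat)
  p <- ft$p.value
  if (exact) {
    nPerms <- factorial(k)^b
    if (nPerms > maxPerms)
      stop(sprintf("(k!)^b = %g exceeds maxPerms; use the asymptotic p", nPerms))
    perms <- .permutationsOf(k)
    stat0 <- ft$statistic
    idx <- rep(1L, b)
    count <- 0L; total <- 0L
    repeat {
      m <- mat
      for (r in seq_len(b)) m[r, ] <- mat[r, perms[[idx[r]]]]
      s <- stats::friedman.test(m)$statistic
      total <- total + 1L
      if (s >= stat0 - 1e-12) count <- count + 1L
      j <- 1L
      while (j <= b) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(perms)) break
        idx[j] <- 1L; j <- j + 1L
      }
      if (j > b) break
    }
    p <- count / total
  }
  out <- .testResult("friedman", "chi_squared", ft$statistic,
                     paste0(b, "x", k), p)
  out$df <- unname(ft$parameter)
  out
}

.permutationsOf <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- .permutationsOf(k - 1)
    for (r in rest) out[[length(out) + 1]] <- c(i, setdiff(seq_len(k), i)[r])
  }
  out
}

#' Bonferroni adjustment
#'
#' \eqn{p' = \min(1, m p)} with m the number of comparisons (defaults to
#' the length of the vector, via [stats::p.adjust()]).
#'
#' @param p numeric p-values in \[0, 1\].
#' @param m number of comparisons.
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Observed-vs-expected feature use tests
#'
#' For each exhibit feature, compares the individuals' observed percentage
#' use (whole study, pooled) against the expected percentage from
#' availability using a Mann-Whitney test, the expected value entering as a
#' constant pseudo-sample of the same length.  P-values are
#' Bonferroni-adjusted across features.
#'
#' @param usage overall [observedUse()] table (stratum "overall").
#' @param map an [ExhibitMap-class].
#' @return data.frame feature, expected_pct, mean_observed_pct, statistic
#'   (W), n, p_raw, p_adjusted.
#' @export
featurePreferenceTests <- function(usage, map) {
  p <- availability(map)
  rows <- list()
  for (f in names(p)) {
    obs <- 100 * usage$r[usage$feature == f]
    exp <- rep(100 * p[[f]], length(obs))
    res <- tryCatch(mannWhitneyTest(obs, exp),
                    error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      feature = f, expected_pct = 100 * p[[f]],
      mean_observed_pct = mean(obs),
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      n = length(obs),
      p_raw = if (is.null(res)) NA_real_ else res$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adjusted <- ifelse(is.na(out$p_raw), NA,
                           bonferroniAdjust(ifelse(is.na(out$p_raw), 0, out$p_raw),
                                            m = sum(!is.na(out$p_raw))))
  out$p_adjusted[is.na(out$p_raw)] <- NA
  out
}

#' Seasonal electivity comparisons
#'
#' Per feature, a Wilcoxon signed-rank test (continuity-corrected) of each
#' individual's warm-season minus cold-season electivity, averaged over the
#' study years; Bonferroni-adjusted across testable features.  Features
#' with identical electivity in both seasons for every individual (e.g.
#' never used at all) are reported with NA.
#'
#' @param electivity [electivityTable()] stratified by season.
#' @return data.frame feature, statistic (V), n, p_raw, p_adjusted.
#' @export
seasonalElectivityTests <- function(electivity) {
  rows <- list()
  for (f in unique(electivity$feature)) {
    s <- electivity[electivity$feature == f, ]
    warm <- s[s$stratum == "warm", ]
    cold <- s[s$stratum == "cold", ]
    ids <- intersect(warm$individual_id, cold$individual_id)
    d <- warm$E_star[match(ids, warm$individual_id)] -
         cold$E_star[match(ids, cold$individual_id)]
    res <- tryCatch(wilcoxonSignedRankTest(d, continuity = TRUE),
                    error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      feature = f,
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      n = length(ids),
      p_raw = if (is.null(res)) NA_real_ else res$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- !is.na(out$p_raw)
  out$p_adjusted <- NA_real_
  out$p_adjusted[ok] <- bonferroniAdjust(out$p_raw[ok], m = sum(ok))
  out
}

#' Time-of-day electivity comparisons
#'
#' Per feature, a Friedman test of electivity across morning / midday /
#' afternoon over individuals (blocks); Bonferroni-adjusted across testable
#' features.  Constant features (no variation in any block) are reported
#' with NA.
#'
#' @param electivity [electivityTable()] stratified by time_block.
#' @return data.frame feature, statistic (chi-squared), df, n, p_raw,
#'   p_adjusted.
#' @export
timeOfDayTests <- function(electivity) {
  blocks <- c("morning", "midday", "afternoon")
  rows <- list()
  for (f in unique(electivity$feature)) {
    s <- electivity[electivity$feature == f & electivity$stratum %in% blocks, ]
    ids <- Reduce(intersect, lapply(blocks, function(b)
      s$individual_id[s$stratum == b]))
    mat <- sapply(blocks, function(b)
      s$E_star[s$stratum == b][match(ids, s$individual_id[s$stratum == b])])
    res <- tryCatch({
      if (length(ids) < 2 || all(apply(mat, 1, stats::var) == 0)) NULL
      else friedmanRankTest(mat)
    }, error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      feature = f,
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      df = if (is.null(res)) NA_real_ else res$df,
      n = length(ids),
      p_raw = if (is.null(res)) NA_real_ else res$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- !is.na(out$p_raw)
  out$p_adjusted <- NA_real_
  out$p_adjusted[ok] <- bonferroniAdjust(out$p_raw[ok], m = sum(ok))
  out
}

#' Paired seasonal permutation test
#'
#' A permutation surrogate for seasonal comparisons of per-individual
#' summaries (e.g. home-range area): the observed mean warm-cold difference
#' is compared against its distribution under random sign flips of each
#' individual's paired difference.
#'
#' @param warm,cold numeric vectors paired by individual.
#' @param nPerm number of sign-flip permutations; default 10000.
#' @param seed optional RNG seed for reproducibility.
#' @return one-row data.frame with statistic_label "mean_diff".
#' @export
seasonalPermutationTest <- function(warm, cold, nPerm = 10000, seed = NULL) {
  stopifnot(length(warm) == length(cold))
  if (!is.null(seed)) set.seed(seed)
  d <- warm - cold
  obs <- mean(d)
  flips <- matrix(sample(c(-1, 1), nPerm * length(d), replace = TRUE),
                  nrow = nPerm)
  null <- as.vector(flips %*% d) / length(d)
  p <- (sum(abs(null) >= abs(obs) - 1e-12) + 1) / (nPerm + 1)
  .testResult("seasonal_permutation", "mean_diff", obs, length(d), p)
}
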