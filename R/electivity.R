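#' @include exhibit-map.R
NULL

#' Observed feature use per individual
#'
#' Assigns every location to an exhibit feature and tabulates each
#' individual's observed use \eqn{r_i} — the proportion of its locations in
#' feature i — optionally stratified by sampling period, season or time of
#' day.  Features never used appear with \eqn{r_i = 0}; individual-strata
#' with no locations are simply absent.
#'
#' @param records normalised location records with columns individual_id,
#'   x, y and (as needed) period, season, time_block.
#' @param map an [ExhibitMap-class].
#' @param stratifyBy one of "overall", "period", "season", "time_block".
#' @return data.frame individual_id, stratum, feature, r, n_locations;
#'   within each individual-stratum the r values sum to 1.
#' @export
observedUse <- function(records, map,
                        stratifyBy = c("overall", "period", "season",
                                       "time_block")) {
  stratifyBy <- match.arg(stratifyBy)
  codes <- names(features(map))
  records$feature <- assignFeature(records$x, records$y, map)
  records$stratum <- if (stratifyBy == "overall") "overall"
                     else records[[stratifyBy]]
  rows <- list()
  for (id in unique(records$individual_id)) {
    sub <- records[records$individual_id == id, ]
    for (st in unique(sub$stratum)) {
      s <- sub[sub$stratum == st, ]
      counts <- table(factor(s$feature, levels = codes))
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = id, stratum = st, feature = codes,
        r = as.numeric(counts) / nrow(s), n_locations = nrow(s),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Vanderploeg-Scavia electivity
#'
#' For one individual-stratum usage vector, computes the selectivity
#' coefficient \eqn{W_i = (r_i / p_i) / \sum_j (r_j / p_j)} and the
#' electivity index \eqn{E^*_i = (W_i - 1/n) / (W_i + 1/n)}, where
#' \eqn{r_i} is observed use, \eqn{p_i} availability and n the number of
#' defined exhibit features.  E* is -1 for features never used, 0 when a
#' feature is used exactly in proportion to its availability, and
#' approaches +1 for strongly preferred features.
#'
#' @param r named numeric vector of observed proportions (names = feature
#'   codes, summing to 1).
#' @param map an [ExhibitMap-class] supplying availability p and n.
#' @return data.frame feature, r, p, W, E_star.
#' @export
electivityIndex <- function(r, map) {
  p <- availability(map)
  codes <- names(p)
  r <- r[codes]
  r[is.na(r)] <- 0
  if (abs(sum(r) - 1) > 1e-8)
    stop("observed proportions must sum to 1")
  ratio <- r / p
  denom <- sum(ratio)
  if (denom == 0) stop("no feature was used: electivity undefined")
  W <- ratio / denom
  n <- length(codes)
  E <- (W - 1 / n) / (W + 1 / n)
  data.frame(feature = codes, r = unname(r), p = unname(p),
             W = unname(W), E_star = unname(E),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Electivity table over a cohort
#'
#' Applies [electivityIndex()] to every individual-stratum of an
#' [observedUse()] table.
#'
#' @param usage data.frame from [observedUse()].
#' @param map an [ExhibitMap-class].
#' @return data.frame individual_id, stratum, feature, r, p, W, E_star.
#' @export
electivityTable <- function(usage, map) {
  rows <- list()
  keys <- unique(usage[c("individual_id", "stratum")])
  for (i in seq_len(nrow(keys))) {
    s <- usage[usage$individual_id == keys$individual_id[i] &
               usage$stratum == keys$stratum[i], ]
    e <- electivityIndex(stats::setNames(s$r, s$feature), map)
    e$individual_id <- keys$individual_id[i]
    e$stratum <- keys$stratum[i]
    rows[[length(rows) + 1]] <- e
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[c("individual_id", "stratum", "feature", "r", "p", "W", "E_star")]
}

#' Group preference summary
#'
#' Per-feature mean and standard error of a chosen electivity-table column
#' (default `E_star`) across individuals, within each stratum.
#'
#' @param electivity data.frame from [electivityTable()].
#' @param value column to summarise ("E_star" or "r").
#' @return data.frame stratum, feature, mean, se, n_individuals.
#' @export
groupPreferenceSummary <- function(electivity, value = "E_star") {
  rows <- list()
  for (st in unique(electivity$stratum)) {
    sub <- electivity[electivity$stratum == st, ]
    for (f in unique(sub$feature)) {
      v <- sub[[value]][sub$feature == f]
      rows[[length(rows) + 1]] <- data.frame(
        stratum = st, feature = f, mean = mean(v),
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n_individuals = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
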