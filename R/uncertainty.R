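# Uncertainty budget for aggregated NEE: per-record random error from flux
# differences under similar meteorological conditions, and bootstrap
# assessments of the u*-filtering and gap-filling components. Components are
# combined assuming independence (variances add, total is the square root).

#' Per-record random flux error from paired similar conditions
#'
#' Pairs of measured records at the same time of day within `delta_days`
#' whose radiation, temperature and vapour-pressure deficit fall inside the
#' similarity windows provide flux differences; their standard deviation
#' divided by sqrt(2) estimates the random measurement error. Because the
#' error typically scales with flux magnitude, the paired differences are
#' pooled in flux-magnitude bins and every measured record inherits the
#' sigma of its bin (records without companions thereby inherit a binned
#' default). Gap-filled records are assigned the same magnitude-binned sigma
#' as the uncertainty of the filled value, so period budgets cover the whole
#' series; set `include_filled = FALSE` to restrict to measured records.
#'
#' @param series Flux tibble with `timestamp`, `nee`, `rg`, `ta`, `vpd` and
#'   quality state.
#' @param delta_days Companion search window in days (default 5).
#' @param rg_tol,ta_tol,vpd_tol Similarity windows: |dRg| < 50 W m-2,
#'   |dTa| < 2.5 degC, |dVPD| < 5 hPa by default.
#' @param n_bins Flux-magnitude bins (default 5).
#' @param min_pairs Minimum pooled pairs per bin before it falls back to the
#'   overall estimate (default 30).
#' @param include_filled Assign binned sigmas to gap-filled records too
#'   (default `TRUE`).
#' @return Numeric vector of per-record sigma (umol m-2 s-1); `NA` for
#'   non-measured records. A warning is raised when no pairs exist at all.
#' @export
random_error <- function(series, delta_days = 5, rg_tol = 50, ta_tol = 2.5,
                         vpd_tol = 5, n_bins = 5, min_pairs = 30,
                         include_filled = TRUE) {
  series <- ensure_quality_state(series)
  n <- nrow(series)
  sigma <- rep(NA_real_, n)
  meas <- series$quality_state == "measured" & !is.na(series$nee)
  assignable <- if (include_filled) {
    meas | (series$quality_state == "gap_filled" & !is.na(series$nee))
  } else meas
  tod <- format(series$timestamp, "%H:%M")
  day <- as.numeric(as.Date(series$timestamp))
  pair_diff <- c(); pair_mag <- c()
  for (grp in split(which(meas), tod[meas])) {
    if (length(grp) < 2) next
    d <- day[grp]
    nee <- series$nee[grp]; rg <- series$rg[grp]
    ta <- series$ta[grp]; vpd <- series$vpd[grp]
    dd <- outer(d, d, "-")
    ok <- dd > 0 & dd <= delta_days &
      abs(outer(rg, rg, "-")) < rg_tol &
      abs(outer(ta, ta, "-")) < ta_tol &
      abs(outer(vpd, vpd, "-")) < vpd_tol
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    pair_diff <- c(pair_diff, nee[idx[, 1]] - nee[idx[, 2]])
    pair_mag <- c(pair_mag, (abs(nee[idx[, 1]]) + abs(nee[idx[, 2]])) / 2)
  }
  if (length(pair_diff) == 0) {
    warning("no similar pairs anywhere; all records use the overall default")
    sigma[assignable] <- stats::median(abs(series$nee[meas]), na.rm = TRUE)
    return(sigma)
  }
  overall <- sd(pair_diff) / sqrt(2)
  br <- unique(quantile(pair_mag, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) > 2) {
    pbin <- cut(pair_mag, br, include.lowest = TRUE, labels = FALSE)
    bin_sigma <- vapply(seq_len(length(br) - 1), function(b) {
      d <- pair_diff[pbin == b]
      if (length(d) >= min_pairs) sd(d) / sqrt(2) else overall
    }, numeric(1))
    rbin <- cut(abs(series$nee), br, include.lowest = TRUE, labels = FALSE)
    sigma[assignable] <- bin_sigma[rbin[assignable]]
    sigma[assignable & is.na(sigma)] <- overall
  } else {
    sigma[assignable] <- overall
  }
  sigma
}

#' Bootstrap uncertainty of u* filtering and gap-filling
#'
#' Two bootstrap assessments, each of `n_boot` iterations, recalculate the
#' aggregated NEE series: (1) the u* component re-draws the threshold from
#' its bootstrap distribution, re-applies the filter, and predicts the newly
#' screened records with the baseline gap-filling model; (2) the gap-filling
#' component keeps the point-estimate threshold and refits the filler on a
#' resample of the training records. The SD across the `n_boot` recalculated
#' aggregate series gives each component's SD; the recalculated series are
#' retained for audit.
#'
#' @param series Screened, storage-corrected flux tibble (before u*
#'   filtering).
#' @param ustar_result A [ustar_threshold()] result (supplies the bootstrap
#'   threshold distribution).
#' @param n_boot Iterations per component (default 100).
#' @param period Aggregation period (`"year"` or `"week"`).
#' @param predictors Passed to [gapfill()].
#' @param n_trees Ensemble size for the bootstrap refits (default 50; a
#'   reduced count keeps the resample loop tractable).
#' @param n_trees_baseline Ensemble size for the baseline filler whose
#'   series is the final estimate (default 100).
#' @param seed Integer seed.
#' @return List with `sigma_ustar`, `sigma_gapfill` (Mg CO2 ha-1 period-1,
#'   vectors over periods), `aggregates_ustar` and `aggregates_gapfill`
#'   (n_boot x n_periods matrices, the audit trail).
#' @export
bootstrap_uncertainty <- function(series, ustar_result, n_boot = 100,
                                  period = "year",
                                  predictors = c("rg", "ta", "vpd"),
                                  n_trees = 50, n_trees_baseline = 100,
                                  seed = 1L) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  stopifnot(inherits(ustar_result, "ustar_result"))
  set.seed(seed)

  base_filtered <- apply_ustar_filter(series, ustar_result$threshold)
  base <- gapfill(base_filtered, predictors = predictors,
                  n_trees = n_trees_baseline, seed = seed)
  mfit <- attr(base, "model")
  feat <- gapfill_features(series, predictors)
  usable <- complete.cases(feat)
  pred_all <- rep(NA_real_, nrow(series))
  pred_all[usable] <- predict(mfit, feat[usable, , drop = FALSE],
                              num.threads = 1)$predictions

  len_days <- if (period == "week") 7 else 365
  pidx <- floor((as.numeric(series$timestamp) -
                   as.numeric(series$timestamp[1])) / (len_days * 86400))
  agg_of <- function(s) {
    as.numeric(rowsum(s$nee, pidx)) * UMOL_HALFHOUR_TO_MG_CO2_HA
  }

  n_periods <- length(agg_of(base))

  # --- u* component: vary the threshold, filler fixed -----------------
  thr_draws <- sample(ustar_result$boot, n_boot, replace = TRUE)
  agg_u <- matrix(NA_real_, n_boot, n_periods)
  for (b in seq_len(n_boot)) {
    s <- apply_ustar_filter(series, thr_draws[b])
    fill <- s$quality_state %in% c("gap", "screened_out")
    s$nee[fill] <- pred_all[fill]
    s$quality_state[fill] <- "gap_filled"
    drop <- is.na(s$nee)
    if (any(drop)) s$nee[drop] <- pred_all[drop]
    s$nee[is.na(s$nee)] <- 0
    agg_u[b, ] <- agg_of(s)
  }

  # --- gap-fill component: fixed threshold, refit on resamples --------
  train <- which(base_filtered$quality_state == "measured" &
                   !is.na(base_filtered$nee) & usable)
  agg_g <- matrix(NA_real_, n_boot, n_periods)
  for (b in seq_len(n_boot)) {
    rs <- sample.int(length(train), replace = TRUE)
    s <- gapfill(base_filtered, predictors = predictors, n_trees = n_trees,
                 seed = seed + b, resample_train = rs)
    s$nee[is.na(s$nee)] <- pred_all[is.na(s$nee)]
    agg_g[b, ] <- agg_of(s)
  }

  list(
    sigma_ustar = apply(agg_u, 2, sd),
    sigma_gapfill = apply(agg_g, 2, sd),
    aggregates_ustar = agg_u,
    aggregates_gapfill = agg_g,
    baseline = base
  )
}

#' Assemble an uncertainty budget
#'
#' @param sigma_random,sigma_ustar,sigma_gapfill Component SDs (Mg CO2 ha-1
#'   per aggregation period).
#' @return Tibble with the components and `sigma_total` (root of summed
#'   variances).
#' @export
uncertainty_budget <- function(sigma_random, sigma_ustar, sigma_gapfill) {
  stopifnot(all(sigma_random >= 0, na.rm = TRUE),
            all(sigma_ustar >= 0, na.rm = TRUE),
            all(sigma_gapfill >= 0, na.rm = TRUE))
  tibble::tibble(
    sigma_random = sigma_random, sigma_ustar = sigma_ustar,
    sigma_gapfill = sigma_gapfill,
    sigma_total = sqrt(sigma_random^2 + sigma_ustar^2 + sigma_gapfill^2)
  )
}
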