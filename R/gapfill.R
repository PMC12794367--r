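# Gap-filling with a bagged ensemble of regression trees (random forest base
# estimator). Predictors are the meteorological drivers plus cyclic
# encodings of hour-of-day and day-of-year, so the diurnal and seasonal
# cycles are available to the trees without discontinuities.

gapfill_features <- function(series, predictors) {
  hour <- as.numeric(format(series$timestamp, "%H")) +
    as.numeric(format(series$timestamp, "%M")) / 60
  doy <- as.numeric(format(series$timestamp, "%j"))
  feat <- data.frame(
    hour_sin = sin(2 * pi * hour / 24), hour_cos = cos(2 * pi * hour / 24),
    doy_sin = sin(2 * pi * doy / 365), doy_cos = cos(2 * pi * doy / 365)
  )
  for (p in predictors) {
    if (!p %in% names(series)) stop("predictor entirely missing: ", p)
    v <- series[[p]]
    if (all(is.na(v))) stop("predictor entirely missing: ", p)
    feat[[p]] <- v
  }
  feat
}

#' Gap-fill a flux series with a bagged regression-tree ensemble
#'
#' Trains a random-forest regressor (an ensemble of trees fit on bootstrap
#' resamples of the valid records) of NEE on meteorological predictors and
#' cyclic time encodings, then replaces gaps and screened-out records by the
#' ensemble-mean prediction. Filled records are flagged `"gap_filled"`; the
#' original measured values are retained in `nee_orig`.
#'
#' @param series Flux tibble with `timestamp`, `nee`, quality state, and the
#'   predictor columns.
#' @param predictors Meteorological predictor columns (default `rg`, `ta`,
#'   `vpd`).
#' @param n_trees Ensemble size (default 100).
#' @param seed Integer seed.
#' @param min_train Minimum number of training records (default 100).
#' @param resample_train Optional integer vector of training-row indices
#'   (with replacement) — used by the bootstrap uncertainty assessment to
#'   refit the filler on a resample.
#' @param model_only If `TRUE`, return the fitted ranger model and features
#'   without modifying the series.
#' @return The filled series with attributes `oob_r2` (out-of-bag R^2) and
#'   `model` unless `model_only`.
#' @export
gapfill <- function(series, predictors = c("rg", "ta", "vpd"),
                    n_trees = 100, seed = 1L, min_train = 100,
                    resample_train = NULL, model_only = FALSE) {
  series <- ensure_quality_state(series)
  if (!"nee" %in% names(series)) stop("run add_storage() first (no nee column)")
  feat <- gapfill_features(series, predictors)
  usable <- complete.cases(feat)
  train <- which(series$quality_state == "measured" & !is.na(series$nee) &
                   usable)
  if (length(train) < min_train) {
    stop(sprintf("too few training records: %d (< %d)", length(train),
                 min_train))
  }
  tr <- if (is.null(resample_train)) train else train[resample_train]
  df <- cbind(nee = series$nee[tr], feat[tr, , drop = FALSE])
  fit <- ranger::ranger(nee ~ ., data = df, num.trees = n_trees,
                        seed = seed, num.threads = 1,
                        min.node.size = 5)
  if (model_only) return(list(model = fit, features = feat, train = train))

  fill <- which(series$quality_state %in% c("gap", "screened_out") & usable)
  out <- series
  out$nee_orig <- series$nee
  if (length(fill)) {
    pred <- predict(fit, feat[fill, , drop = FALSE],
                    num.threads = 1)$predictions
    out$nee[fill] <- pred
    out$quality_state[fill] <- "gap_filled"
  }
  attr(out, "oob_r2") <- fit$r.squared
  attr(out, "model") <- fit
  attr(out, "truth") <- attr(series, "truth")
  out
}
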