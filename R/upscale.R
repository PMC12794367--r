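# Satellite-proxy upscaling: seasonal origin-constrained SIF -> GPP slopes,
# a four-parameter temperature/water-index respiration model, 8-day NEE
# maps, tower validation with outlier-robust origin-constrained regression,
# and the median-ratio spatial extrapolation factor.

#' Fit seasonal SIF-to-GPP slopes
#'
#' Per-season least-squares slope through the origin (`GPP = slope * SIF`),
#' with R^2 and residual SE per season. The origin-constrained slope is
#' \eqn{\sum xy / \sum x^2}.
#'
#' @param samples Tibble with `season`, `sif`, `gpp` (g C m-2 day-1).
#' @param min_n Minimum samples per season (default 3).
#' @return A `sif_gpp_model` with a `seasons` tibble (`season`, `slope`,
#'   `r_squared`, `rse`, `n`).
#' @export
fit_sif_gpp <- function(samples, min_n = 3) {
  stopifnot(all(c("season", "sif", "gpp") %in% names(samples)))
  seasons <- samples |>
    dplyr::filter(!is.na(.data$sif), !is.na(.data$gpp)) |>
    dplyr::group_by(.data$season) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_n) stop("too few samples in season ", key$season)
      if (all(d$sif == 0)) stop("all-zero SIF in season ", key$season,
                                ": slope undefined")
      slope <- sum(d$sif * d$gpp) / sum(d$sif^2)
      res <- d$gpp - slope * d$sif
      tibble::tibble(
        slope = slope,
        r_squared = 1 - sum(res^2) / sum((d$gpp - mean(d$gpp))^2),
        rse = sqrt(sum(res^2) / (nrow(d) - 1)),
        n = nrow(d))
    }) |>
    dplyr::ungroup()
  structure(list(seasons = seasons), class = "sif_gpp_model")
}

#' @export
print.sif_gpp_model <- function(x, ...) {
  cat("<sif_gpp_model>\n")
  print(x$seasons)
  invisible(x)
}

#' @rdname fit_sif_gpp
#' @param x A `sif_gpp_model`.
#' @param ... Unused.
#' @export
tidy.sif_gpp_model <- function(x, ...) x$seasons

#' Predict GPP from SIF
#'
#' Negative SIF is clamped to zero before the proportional prediction.
#'
#' @param model A `sif_gpp_model`.
#' @param sif SIF values (vector or `grid_raster`).
#' @param season Single season label present in the model.
#' @return GPP (g C m-2 day-1), same shape as `sif`.
#' @export
predict_gpp <- function(model, sif, season) {
  row <- model$seasons[model$seasons$season == season, ]
  if (nrow(row) != 1) stop("unknown season: ", season)
  f <- function(s) row$slope * pmax(s, 0)
  if (inherits(sif, "grid_raster")) {
    out <- sif; out$values <- f(sif$values); out
  } else f(sif)
}

#' Four-parameter respiration model object
#'
#' Respiration form \eqn{RECO = R_0 W \exp(E_0 (1/(T_{ref}-T_0) -
#' 1/(LST-T_0)))} with water scalar \eqn{W = (1 + k\,LSWI)/(1 +
#' k\,LSWI_{max})}. This constructor is the single place the functional form
#' lives, so an alternative form can be swapped in.
#'
#' @param r0 Base respiration (g C m-2 day-1).
#' @param k Water-index sensitivity.
#' @param lswimax Water-index value at which the water scalar is 1.
#' @param e0 Temperature sensitivity (K).
#' @param tref,t0 Reference temperatures (K).
#' @return A `reco_model`.
#' @export
reco_model <- function(r0, k, lswimax, e0, tref = LT_TREF_K, t0 = LT_T0_K) {
  stopifnot(r0 > 0, e0 > 0, lswimax > -1, lswimax <= 1)
  structure(list(r0 = r0, k = k, lswimax = lswimax, e0 = e0,
                 tref = tref, t0 = t0, fit = NULL),
            class = "reco_model")
}

reco_eval <- function(m, lst, lswi) {
  w <- (1 + m$k * lswi) / (1 + m$k * m$lswimax)
  m$r0 * w * exp(m$e0 * (1 / (m$tref - m$t0) - 1 / (lst - m$t0)))
}

#' Fit the respiration model by nonlinear least squares
#'
#' Bounded multi-start Levenberg-Marquardt fits. The water-scalar ceiling
#' `LSWImax` is taken as the observed maximum water index by default: in
#' this model family the likelihood is exactly flat along the
#' (`R0`, `LSWImax`) ridge (`W` only ever appears as `R0/(1 + k LSWImax)`
#' times `(1 + k LSWI)`), so the ceiling is a site property read off the
#' data, not a free coefficient. Set `fit_lswimax = TRUE` to fit it anyway.
#' The best-converged start (lowest residual sum of squares) is returned
#' with convergence diagnostics.
#'
#' @param samples Tibble with `lst` (K), `lswi`, `reco` (g C m-2 day-1).
#' @param starts Data frame of starting values (columns `r0`, `k`, `e0`,
#'   plus `lswimax` when it is fitted); a default grid of starts is used
#'   when `NULL`.
#' @param fit_lswimax Fit the water-scalar ceiling as a free parameter
#'   (default `FALSE`: use `max(lswi)`).
#' @param lower,upper Parameter bounds.
#' @param tref,t0 Fixed reference temperatures (K).
#' @return A `reco_model` whose `fit` element holds `r_squared`, `rse`,
#'   `converged`, `rss`, `n`, `start_used`.
#' @export
fit_reco <- function(samples, starts = NULL, fit_lswimax = FALSE,
                     lower = c(r0 = 0.05, k = 0.01, lswimax = 0.05,
                               e0 = 30),
                     upper = c(r0 = 30, k = 5, lswimax = 1, e0 = 500),
                     tref = LT_TREF_K, t0 = LT_T0_K) {
  stopifnot(all(c("lst", "lswi", "reco") %in% names(samples)))
  df <- samples[complete.cases(samples[c("lst", "lswi", "reco")]), ]
  if (nrow(df) < 10) stop("need at least 10 complete samples")
  if (any(df$lst <= t0)) stop("LST at or below the model's T0")
  pars <- if (fit_lswimax) c("r0", "k", "lswimax", "e0") else
    c("r0", "k", "e0")
  if (is.null(starts)) {
    starts <- if (fit_lswimax) {
      expand.grid(r0 = c(1, 2.5, 5), k = c(0.3, 0.8),
                  lswimax = c(0.5, 0.9), e0 = c(100, 200, 320))
    } else {
      expand.grid(r0 = c(1, 2.5, 5), k = c(0.3, 0.8),
                  e0 = c(100, 200, 320))
    }
  }
  lswimax_fixed <- max(df$lswi)
  form <- if (fit_lswimax) {
    reco ~ r0 * (1 + k * lswi) / (1 + k * lswimax) *
      exp(e0 * (1 / (tref - t0) - 1 / (lst - t0)))
  } else {
    reco ~ r0 * (1 + k * lswi) / (1 + k * lswimax_fixed) *
      exp(e0 * (1 / (tref - t0) - 1 / (lst - t0)))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form, data = df, start = as.list(starts[i, pars]),
        lower = lower[pars], upper = upper[pars],
        control = nls.control(maxiter = 300, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss, start = i,
                   converged = fit$convInfo$isConv)
    }
  }
  if (is.null(best)) {
    stop("respiration fit failed to converge from any start")
  }
  cf <- coef(best$fit)
  res <- stats::resid(best$fit)
  m <- reco_model(cf[["r0"]], cf[["k"]],
                  if (fit_lswimax) cf[["lswimax"]] else lswimax_fixed,
                  cf[["e0"]], tref, t0)
  m$fit <- list(
    r_squared = 1 - best$rss / sum((df$reco - mean(df$reco))^2),
    rse = sqrt(best$rss / (nrow(df) - 4)),
    rss = best$rss, n = nrow(df), converged = best$converged,
    start_used = best$start)
  m
}

#' @export
print.reco_model <- function(x, ...) {
  cat(sprintf("<reco_model> R0 = %.3f, k = %.3f, LSWImax = %.3f, E0 = %.2f K\n",
              x$r0, x$k, x$lswimax, x$e0))
  if (!is.null(x$fit)) {
    cat(sprintf("  fit: R^2 %.3f, RSE %.3f (n = %d)\n",
                x$fit$r_squared, x$fit$rse, x$fit$n))
  }
  invisible(x)
}

#' @rdname fit_reco
#' @param x A `reco_model`.
#' @param ... Unused.
#' @export
tidy.reco_model <- function(x, ...) {
  tibble::tibble(term = c("r0", "k", "lswimax", "e0"),
                 estimate = c(x$r0, x$k, x$lswimax, x$e0))
}

#' @rdname fit_reco
#' @export
glance.reco_model <- function(x, ...) {
  if (is.null(x$fit)) return(tibble::tibble())
  tibble::tibble(r_squared = x$fit$r_squared, rse = x$fit$rse,
                 n = x$fit$n, converged = x$fit$converged)
}

#' Predict respiration from LST and LSWI
#'
#' Cells with LST at or below the model's T0 are returned missing and
#' counted.
#'
#' @param model A `reco_model`.
#' @param lst LST (K), vector or `grid_raster`.
#' @param lswi LSWI, same shape as `lst`.
#' @return RECO (g C m-2 day-1) with attribute `n_invalid`.
#' @export
predict_reco <- function(model, lst, lswi) {
  raster_in <- inherits(lst, "grid_raster")
  lv <- if (raster_in) lst$values else lst
  wv <- if (inherits(lswi, "grid_raster")) lswi$values else lswi
  bad <- !is.na(lv) & lv <= model$t0
  lv[bad] <- NA
  out <- reco_eval(model, lv, wv)
  if (raster_in) {
    r <- lst; r$values <- out
    attr(r, "n_invalid") <- sum(bad)
    r
  } else {
    attr(out, "n_invalid") <- sum(bad)
    out
  }
}

#' NEE as the difference between respiration and assimilation
#'
#' @param gpp,reco GPP and RECO (`grid_raster`s or vectors), co-registered /
#'   equal length.
#' @return NEE = RECO - GPP; missing propagates.
#' @export
compute_nee <- function(gpp, reco) {
  if (inherits(gpp, "grid_raster")) {
    if (!gr_same_grid(gpp, reco)) stop("GPP and RECO are not co-registered")
    out <- gpp
    out$values <- reco$values - gpp$values
    out
  } else {
    if (length(gpp) != length(reco)) stop("length mismatch")
    reco - gpp
  }
}

#' Downscale a coarse raster to a fine grid
#'
#' Default bilinear interpolation of coarse cell-centre values to fine cell
#' centres; the optional predictor-weighted mode redistributes each coarse
#' cell's value proportionally to a fine predictor while conserving the
#' coarse-cell mean.
#'
#' @param coarse Coarse `grid_raster`.
#' @param target Fine `grid_raster` defining the output grid (values
#'   ignored unless it is the predictor).
#' @param predictor Optional fine `grid_raster` on the target grid; when
#'   given, conservative redistribution is used.
#' @return Fine `grid_raster`.
#' @export
downscale <- function(coarse, target, predictor = NULL) {
  cc <- gr_coords(coarse)
  tc <- gr_coords(target)
  if (max(tc$x) < min(cc$x) - coarse$cell_size ||
      min(tc$x) > max(cc$x) + coarse$cell_size ||
      max(tc$y) < min(cc$y) - coarse$cell_size ||
      min(tc$y) > max(cc$y) + coarse$cell_size) {
    stop("grids do not overlap")
  }
  out <- target
  if (is.null(predictor)) {
    # pracma::interp2 expects ascending axes; rows are north->south
    z <- coarse$values[rev(seq_len(nrow(coarse$values))), , drop = FALSE]
    xq <- rep(tc$x, each = length(tc$y))
    yq <- rep(tc$y, length(tc$x))
    zi <- pracma::interp2(cc$x, sort(cc$y), z,
                          pmin(pmax(xq, min(cc$x)), max(cc$x)),
                          pmin(pmax(yq, min(cc$y)), max(cc$y)),
                          method = "linear")
    out$values <- matrix(zi, length(tc$y), length(tc$x))
  } else {
    stopifnot(gr_same_grid(target, predictor))
    # map each fine cell to its containing coarse cell
    row_of <- sapply(tc$y, function(y) which.min(abs(cc$y - y)))
    col_of <- sapply(tc$x, function(x) which.min(abs(cc$x - x)))
    vals <- matrix(NA_real_, length(tc$y), length(tc$x))
    p <- predictor$values
    for (i in unique(row_of)) for (j in unique(col_of)) {
      sel_r <- which(row_of == i); sel_c <- which(col_of == j)
      block <- p[sel_r, sel_c, drop = FALSE]
      mb <- mean(block, na.rm = TRUE)
      if (!is.finite(mb) || mb == 0) {
        vals[sel_r, sel_c] <- coarse$values[i, j]
      } else {
        vals[sel_r, sel_c] <- coarse$values[i, j] * block / mb
      }
    }
    out$values <- vals
  }
  out
}

#' Hampel filter over a series
#'
#' Rolling-median outlier detector: a point is an outlier when it deviates
#' from the window median by more than `k` scaled median absolute
#' deviations (1.4826 MAD).
#'
#' @param x Numeric series.
#' @param window Half-window in samples (the window spans `2*window + 1`
#'   points), default 7.
#' @param k Threshold in scaled MADs, default 3.
#' @return Logical vector, `TRUE` where `x` is an outlier.
#' @export
hampel_outliers <- function(x, window = 7, k = 3) {
  n <- length(x)
  out <- rep(FALSE, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - window); hi <- min(n, i + window)
    w <- x[lo:hi]
    med <- median(w, na.rm = TRUE)
    s <- 1.4826 * median(abs(w - med), na.rm = TRUE)
    if (!is.finite(s) || is.na(x[i])) next
    dev <- abs(x[i] - med)
    # zero-MAD convention: any genuine deviation from the window median is
    # an outlier when more than half the window is constant
    out[i] <- if (s > 0) dev > k * s else dev > 1e-8 * max(1, abs(med))
  }
  out
}

#' Validate predicted against observed fluxes
#'
#' Removes outlier pairs with a Hampel filter on the paired differences,
#' then fits an origin-constrained regression `pred = beta * obs` and
#' reports the slope, R^2 about the 1:1 line, RMSE and mean bias.
#'
#' @param predicted,observed Paired flux series (same cadence).
#' @param hampel_window,hampel_k Hampel filter parameters (defaults 7, 3).
#' @return A `validation_stats` tibble row: `beta`, `r_squared`, `rmse`,
#'   `bias`, `n`, `outliers_removed`.
#' @export
validate_fluxes <- function(predicted, observed, hampel_window = 7,
                            hampel_k = 3) {
  stopifnot(length(predicted) == length(observed))
  ok <- !is.na(predicted) & !is.na(observed)
  p <- predicted[ok]; o <- observed[ok]
  out <- hampel_outliers(p - o, hampel_window, hampel_k)
  p2 <- p[!out]; o2 <- o[!out]
  if (length(p2) < 3) stop("fewer than 3 pairs after outlier filtering")
  beta <- sum(p2 * o2) / sum(o2^2)
  r2 <- 1 - sum((p2 - o2)^2) / sum((o2 - mean(o2))^2)
  structure(tibble::tibble(
    beta = beta, r_squared = r2,
    rmse = sqrt(mean((p2 - o2)^2)), bias = mean(p2 - o2),
    n = length(p2), outliers_removed = sum(out)),
    class = c("validation_stats", "tbl_df", "tbl", "data.frame"))
}

#' Spatial extrapolation weighting factor
#'
#' Ratio of the medians (2nd quartiles) of the per-pixel historical mean NEE
#' over an eco-functional cluster and over the tower footprint:
#' `pext = Q2(NEE_EFC) / Q2(NEE_f)`.
#'
#' @param nee_efc Per-pixel historical mean NEE over the EFC.
#' @param nee_footprint Per-pixel historical mean NEE over the tower
#'   footprint.
#' @param efc_id Optional EFC identifier recorded on the result.
#' @param date Computation date (default today); the factor is valid for
#'   `validity_days` from this date.
#' @param validity_days Validity window (default 183 days, a six-month
#'   update cycle).
#' @return A `pext_factor`: `value`, `q2_efc`, `q2_footprint`, `efc_id`,
#'   `date`, `valid_until`.
#' @export
compute_pext <- function(nee_efc, nee_footprint, efc_id = NA,
                         date = Sys.Date(), validity_days = 183) {
  nee_efc <- nee_efc[!is.na(nee_efc)]
  nee_footprint <- nee_footprint[!is.na(nee_footprint)]
  if (length(nee_efc) == 0 || length(nee_footprint) == 0) {
    stop("both NEE populations must be non-empty")
  }
  q2f <- median(nee_footprint)
  if (q2f == 0) stop("footprint median NEE is zero: factor undefined")
  q2e <- median(nee_efc)
  structure(list(value = q2e / q2f, q2_efc = q2e, q2_footprint = q2f,
                 efc_id = efc_id, date = as.Date(date),
                 valid_until = as.Date(date) + validity_days),
            class = "pext_factor")
}

#' @export
print.pext_factor <- function(x, ...) {
  cat(sprintf("<pext_factor> %.3f = %.3f / %.3f (EFC %s, valid until %s)\n",
              x$value, x$q2_efc, x$q2_footprint, as.character(x$efc_id),
              format(x$valid_until)))
  invisible(x)
}

#' Validation scatter plot
#'
#' @param predicted,observed Paired series.
#' @param stats Optional [validate_fluxes()] output used for the subtitle.
#' @return A ggplot with the identity line and the origin-constrained fit.
#' @export
plot_validation <- function(predicted, observed, stats = NULL) {
  df <- tibble::tibble(observed = observed, predicted = predicted)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$observed,
                                        y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2)
  if (!is.null(stats)) {
    p <- p + ggplot2::geom_abline(slope = stats$beta, intercept = 0,
                                  color = "red") +
      ggplot2::labs(subtitle = sprintf("beta = %.2f, R2 = %.2f, RMSE = %.2f",
                                       stats$beta, stats$r_squared,
                                       stats$rmse))
  }
  p + ggplot2::labs(x = "Observed", y = "Predicted")
}
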