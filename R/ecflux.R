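# Half-hourly NEE post-processing: quality screening, storage addition,
# u*-filter application, and aggregation to weekly/annual CO2 budgets.
# Screening never alters values — records carry a `quality_state`
# ("measured", "screened_out", "gap", "gap_filled") and a `screen_reason`
# so audit counts stay exact.

ensure_quality_state <- function(series) {
  if (!"quality_state" %in% names(series)) {
    series$quality_state <- ifelse(is.na(series$fc), "gap", "measured")
    series$screen_reason <- NA_character_
  }
  series
}

#' Quality-screen a flux series
#'
#' Marks records with quality flag 2 or turbulent flux outside the physical
#' range as screened-out. Values are retained for audit; only the quality
#' state changes.
#'
#' @param series Flux tibble with at least `fc` (umol CO2 m-2 s-1) and `qc`
#'   (0/1/2 quality flag).
#' @param flux_limit Physical range limit (umol m-2 s-1); records with
#'   `|fc| > flux_limit` are screened. Default 50.
#' @return The series with updated `quality_state` / `screen_reason`.
#' @export
qc_screen <- function(series, flux_limit = 50) {
  if (!all(series$qc %in% c(0L, 1L, 2L) | is.na(series$qc))) {
    stop("quality flags must be 0, 1 or 2")
  }
  series <- ensure_quality_state(series)
  bad_qc <- !is.na(series$qc) & series$qc == 2L
  bad_range <- !is.na(series$fc) & abs(series$fc) > flux_limit
  hit <- (bad_qc | bad_range) & series$quality_state == "measured"
  series$quality_state[hit] <- "screened_out"
  series$screen_reason[hit] <- ifelse(bad_qc[hit], "qc_flag", "range")
  series
}

#' Add storage terms to turbulent CO2 fluxes
#'
#' NEE per record is the turbulent flux plus the storage term. A missing
#' storage column (or all-missing values where flux exists) is treated as
#' zero with a warning.
#'
#' @param series Flux tibble with `fc` and optionally `sc`.
#' @return The series with an `nee` column (umol CO2 m-2 s-1).
#' @export
add_storage <- function(series) {
  series <- ensure_quality_state(series)
  if (!"sc" %in% names(series) || all(is.na(series$sc[!is.na(series$fc)]))) {
    warning("no storage terms available; NEE = turbulent flux")
    series$nee <- series$fc
  } else {
    sc <- ifelse(is.na(series$sc) & !is.na(series$fc), 0, series$sc)
    series$nee <- series$fc + sc
  }
  series
}

#' Apply a u* threshold filter
#'
#' Nighttime records with friction velocity below the threshold are marked
#' screened-out.
#'
#' @param series Flux tibble with `ustar`, `rg` and a quality state.
#' @param threshold u* threshold (m s-1), >= 0.
#' @param night_rg Radiation threshold defining night (W m-2).
#' @return The series with updated quality state.
#' @export
apply_ustar_filter <- function(series, threshold, night_rg = 10) {
  stopifnot(threshold >= 0)
  series <- ensure_quality_state(series)
  hit <- is_night(series$rg, night_rg) & !is.na(series$ustar) &
    series$ustar < threshold & series$quality_state == "measured"
  series$quality_state[hit] <- "screened_out"
  series$screen_reason[hit] <- "ustar"
  series
}

#' Aggregate a gap-free NEE series to periodic CO2 budgets
#'
#' Sums half-hourly NEE over half-open periods and converts
#' umol CO2 m-2 s-1 to Mg CO2 ha-1 period-1 (x 1800 s x 44.01 g mol-1 x
#' 1e-6 x 1e-2). Requires a gap-free series (run [gapfill()] first).
#'
#' @param series Flux tibble with `timestamp`, `nee`, `quality_state`.
#' @param period `"week"` (7-day blocks from the series start) or `"year"`
#'   (365-day blocks).
#' @param sigma_random Optional per-record random-error SDs (from
#'   [random_error()]). The per-period SD is computed per diurnal stratum
#'   (night / day, since the filler predicts night gaps from night-like
#'   training data) as the root of the summed variances over measured
#'   records scaled by `n_stratum / n_measured_stratum`, and the strata are
#'   combined in quadrature: filled records are predictions of a model
#'   trained on the same measured sample, so their mean error moves with
#'   the measured noise of their stratum rather than independently. With
#'   no filled records this reduces to the plain independent sum.
#' @return Tibble with `period`, `start`, `end`, `nee` (Mg CO2 ha-1
#'   period-1), `n`, `frac_gapfilled`, and `sd_random` when `sigma_random`
#'   is given.
#' @export
aggregate_flux <- function(series, period = c("week", "year"),
                           sigma_random = NULL) {
  period <- match.arg(period)
  if (anyNA(series$nee)) stop("series still contains gaps; gap-fill first")
  len_days <- if (period == "week") 7 else 365
  rec_per <- len_days * 48
  idx <- floor((as.numeric(series$timestamp) -
                  as.numeric(series$timestamp[1])) / (len_days * 86400))
  conv <- UMOL_HALFHOUR_TO_MG_CO2_HA
  df <- tibble::tibble(idx = idx, nee = series$nee,
                       ts = series$timestamp,
                       measured = series$quality_state == "measured",
                       filled = series$quality_state == "gap_filled",
                       night = if ("rg" %in% names(series))
                         is_night(series$rg) else FALSE)
  if (!is.null(sigma_random)) df$sig2 <- sigma_random^2
  stratum_sd <- function(sig2, measured) {
    # correlated propagation within a stratum: filled values inherit the
    # stratum's measured noise mean
    sqrt(sum(sig2[measured], na.rm = TRUE)) *
      (length(sig2) / max(sum(measured), 1))
  }
  out <- df |>
    dplyr::group_by(.data$idx) |>
    dplyr::summarise(
      start = min(.data$ts), end = max(.data$ts) + 1800,
      nee = sum(.data$nee) * conv, n = dplyr::n(),
      frac_gapfilled = mean(.data$filled),
      sd_random = if (!is.null(sigma_random)) sqrt(
        stratum_sd(.data$sig2[.data$night], .data$measured[.data$night])^2 +
        stratum_sd(.data$sig2[!.data$night], .data$measured[!.data$night])^2
      ) * conv else NA_real_,
      .groups = "drop") |>
    dplyr::rename(period = "idx") |>
    dplyr::mutate(period = .data$period + 1L)
  out
}

#' Combine independent uncertainty components
#'
#' Components are assumed independent: variances add and the total is the
#' square root of the sum.
#'
#' @param components Numeric vector of component SDs (common units).
#' @return Total SD.
#' @export
propagate <- function(components) {
  if (any(components < 0, na.rm = TRUE)) stop("negative uncertainty component")
  sqrt(sum(components^2, na.rm = TRUE))
}

#' Weekly flux plot
#'
#' @param aggregates Output of [aggregate_flux()] (weekly).
#' @return A ggplot of cumulative weekly NEE with an uncertainty ribbon when
#'   `sd_random` is present.
#' @export
plot_weekly_flux <- function(aggregates) {
  p <- ggplot2::ggplot(aggregates, ggplot2::aes(x = .data$start,
                                                y = .data$nee)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(Mg~CO[2]~ha^-1~week^-1))
  if (!all(is.na(aggregates$sd_random))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$nee - .data$sd_random,
                   ymax = .data$nee + .data$sd_random),
      alpha = 0.25, fill = "grey40")
  }
  p
}
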