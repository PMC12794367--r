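# Friction-velocity threshold detection on nighttime data: seasonal
# temperature classes, u* quantile classes, plateau criterion, and a
# bootstrap over nights for the threshold distribution.

ustar_threshold_once <- function(night, n_temp_classes, n_ustar_classes,
                                 plateau, cor_limit, min_records) {
  seasons <- unique(night$season)
  season_thr <- rep(NA_real_, length(seasons))
  detail <- list()
  for (si in seq_along(seasons)) {
    ns <- night[night$season == seasons[si], ]
    if (nrow(ns) < min_records) next
    tcls <- cut(ns$ta, breaks = quantile(ns$ta, seq(0, 1, length.out =
                                                      n_temp_classes + 1)),
                include.lowest = TRUE, labels = FALSE)
    cls_thr <- rep(NA_real_, n_temp_classes)
    for (tc in seq_len(n_temp_classes)) {
      sel <- which(tcls == tc)
      if (length(sel) < n_ustar_classes * 2) next
      sub <- ns[sel, ]
      # skip classes where temperature and u* are confounded
      if (abs(cor(sub$ta, sub$ustar)) > cor_limit) next
      ucls <- cut(sub$ustar,
                  breaks = unique(quantile(sub$ustar,
                                           seq(0, 1, length.out =
                                                 n_ustar_classes + 1))),
                  include.lowest = TRUE, labels = FALSE)
      present <- sort(unique(ucls))
      mean_flux <- vapply(present, function(u) mean(sub$nee[ucls == u]),
                          numeric(1))
      mean_ustar <- vapply(present, function(u) mean(sub$ustar[ucls == u]),
                           numeric(1))
      nu <- length(present)
      if (nu < 3) next
      thr <- mean_ustar[nu]  # conservative fallback: highest class
      for (i in seq_len(nu - 1)) {
        if (mean_flux[i] >= plateau * mean(mean_flux[(i + 1):nu])) {
          thr <- mean_ustar[i]
          break
        }
      }
      cls_thr[tc] <- thr
    }
    if (any(!is.na(cls_thr))) {
      season_thr[si] <- median(cls_thr, na.rm = TRUE)
    }
    detail[[as.character(seasons[si])]] <- cls_thr
  }
  list(threshold = if (all(is.na(season_thr))) NA_real_ else
    max(season_thr, na.rm = TRUE),
    by_season = setNames(season_thr, seasons), detail = detail)
}

#' Estimate the u* threshold from nighttime fluxes
#'
#' Nighttime records are split by season and into temperature classes;
#' within a class, records are sorted into u* quantile classes and the class
#' threshold is the mean u* of the lowest class whose mean flux reaches
#' `plateau` times the mean of all higher classes. Classes where temperature
#' and u* correlate strongly (|r| > `cor_limit`) are skipped. Class
#' thresholds are aggregated as the median over temperature classes and the
#' maximum over seasons. A bootstrap over nights (sampled with replacement,
#' `n_boot` times) yields the threshold distribution used for the
#' filtering-uncertainty budget.
#'
#' @param series Flux tibble with `timestamp`, `nee`, `ustar`, `ta`, `rg`
#'   and a quality state (run [qc_screen()] and [add_storage()] first).
#' @param n_temp_classes Temperature classes per season (default 6).
#' @param n_ustar_classes u* classes per temperature class (default 20).
#' @param plateau Plateau criterion (default 0.95).
#' @param n_boot Bootstrap repetitions (default 100).
#' @param cor_limit Temperature/u* correlation limit (default 0.4).
#' @param min_records Minimum nighttime records per season (default 200).
#' @param night_rg Radiation threshold defining night (W m-2).
#' @param seed Integer seed for the bootstrap.
#' @return A `ustar_result`: `threshold` (m s-1), `boot` (length `n_boot`
#'   bootstrap thresholds), `by_season`, `detail`.
#' @export
ustar_threshold <- function(series, n_temp_classes = 6, n_ustar_classes = 20,
                            plateau = 0.95, n_boot = 100, cor_limit = 0.4,
                            min_records = 200, night_rg = 10, seed = 1L) {
  series <- ensure_quality_state(series)
  if (!"nee" %in% names(series)) stop("run add_storage() first (no nee column)")
  night <- series[is_night(series$rg, night_rg) &
                    series$quality_state == "measured" &
                    !is.na(series$nee) & !is.na(series$ustar) &
                    !is.na(series$ta), ]
  if (nrow(night) < min_records) {
    stop(sprintf("insufficient nighttime data: %d records (< %d)",
                 nrow(night), min_records))
  }
  night$season <- assign_season(night$timestamp)
  night$night_id <- as.Date(night$timestamp - 12 * 3600)  # group by night

  point <- ustar_threshold_once(night, n_temp_classes, n_ustar_classes,
                                plateau, cor_limit, min_records)
  if (is.na(point$threshold)) {
    stop("u* threshold could not be determined from any season/class")
  }

  set.seed(seed)
  nights <- unique(night$night_id)
  split_idx <- split(seq_len(nrow(night)), night$night_id)
  boot <- vapply(seq_len(n_boot), function(b) {
    pick <- sample(seq_along(nights), replace = TRUE)
    res <- ustar_threshold_once(
      night[unlist(split_idx[pick], use.names = FALSE), ],
      n_temp_classes, n_ustar_classes, plateau, cor_limit, min_records)
    res$threshold
  }, numeric(1))
  boot[is.na(boot)] <- point$threshold

  structure(list(threshold = point$threshold, boot = boot,
                 by_season = point$by_season, detail = point$detail,
                 n_boot = n_boot),
            class = "ustar_result")
}

#' @export
print.ustar_result <- function(x, ...) {
  cat(sprintf("<ustar_result> threshold %.3f m s-1 (bootstrap %d: %.3f-%.3f, median %.3f)\n",
              x$threshold, x$n_boot, min(x$boot), max(x$boot),
              median(x$boot)))
  invisible(x)
}
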