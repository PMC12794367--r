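# Seeded synthetic-data generators. Every pipeline input can be emulated with
# known generative truth: clustered landscapes, half-hourly eddy-covariance
# series driven by Lloyd-Taylor respiration and a light-response GPP with
# planted low-turbulence suppression and gaps, and proportional SIF -> GPP
# satellite series. Generator defaults define the study conditions used by
# the test-suite and the acceptance pipeline.

#' Generative truth for a clustered landscape
#'
#' Describes a synthetic landscape of `k` eco-functional clusters laid out as
#' contiguous patches (nearest-seed tessellation), each with its own
#' vegetation class, elevation and canopy-height distribution and forest
#' fraction.
#'
#' @param nrow,ncol Grid dimensions (cells).
#' @param cell_size Cell size in metres (default 30).
#' @param k Number of clusters.
#' @param veg_class Character vector (length `k`): vegetation class of each
#'   cluster, drawn from a finite vocabulary.
#' @param elev_mean,elev_sd Per-cluster elevation mean/SD (m).
#' @param chm_mean,chm_sd Per-cluster canopy-height mean/SD (m).
#' @param forest_frac Per-cluster forest fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return A `landscape_truth` list.
#' @export
landscape_truth <- function(nrow = 120, ncol = 120, cell_size = 30, k = 3,
                            veg_class = c("evergreen_lowland",
                                          "evergreen_montane",
                                          "deciduous_shrubland")[seq_len(k)],
                            elev_mean = seq(150, 900, length.out = k),
                            elev_sd = rep(60, k),
                            chm_mean = seq(28, 6, length.out = k),
                            chm_sd = rep(2.5, k),
                            forest_frac = rep(0.9, k),
                            seed = 1L) {
  stopifnot(nrow >= 1, ncol >= 1, k >= 1, k <= nrow * ncol,
            length(veg_class) == k, length(elev_mean) == k,
            length(chm_mean) == k, all(forest_frac >= 0 & forest_frac <= 1),
            all(is.finite(elev_mean)), all(is.finite(chm_mean)),
            all(elev_sd >= 0), all(chm_sd >= 0))
  structure(list(nrow = nrow, ncol = ncol, cell_size = cell_size, k = k,
                 veg_class = veg_class, elev_mean = elev_mean,
                 elev_sd = elev_sd, chm_mean = chm_mean, chm_sd = chm_sd,
                 forest_frac = forest_frac, seed = as.integer(seed)),
            class = "landscape_truth")
}

#' Generate a synthetic landscape raster stack
#'
#' Cluster patches are the nearest-seed (Voronoi) regions of `k` random seed
#' cells, giving spatially contiguous clusters. Elevation and canopy height
#' are Gaussian around the cluster means (height truncated at 0); land cover
#' is forest with the cluster's forest fraction. Regeneration with the same
#' seed is bit-identical.
#'
#' @param truth A [landscape_truth()].
#' @return Named list of `grid_raster`s: `veg` (categorical), `elev`, `chm`,
#'   `landcover` (categorical: forest / non_forest), `labels` (true cluster).
#' @export
gen_landscape <- function(truth) {
  stopifnot(inherits(truth, "landscape_truth"))
  set.seed(truth$seed)
  nr <- truth$nrow; nc <- truth$ncol; k <- truth$k
  n <- nr * nc
  # farthest-point seeding keeps patch sizes comparable
  seeds <- sample.int(n, 1)
  if (k > 1) {
    all_r <- (seq_len(n) - 1) %% nr + 1
    all_c <- (seq_len(n) - 1) %/% nr + 1
    for (j in 2:k) {
      dmin <- rep(Inf, n)
      for (s in seeds) {
        ds <- (all_r - all_r[s])^2 + (all_c - all_c[s])^2
        dmin <- pmin(dmin, ds)
      }
      seeds <- c(seeds, which.max(dmin))
    }
  }
  sr <- (seeds - 1) %% nr + 1
  sc <- (seeds - 1) %/% nr + 1
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  lab <- matrix(1L, nr, nc)
  if (k > 1) {
    best <- matrix(Inf, nr, nc)
    for (j in seq_len(k)) {
      d <- (rows - sr[j])^2 + (cols - sc[j])^2
      upd <- d < best
      lab[upd] <- j
      best[upd] <- d[upd]
    }
  }
  # guarantee no empty cluster (possible with coincident-distance ties)
  for (j in seq_len(k)) if (!any(lab == j)) lab[sr[j], sc[j]] <- j

  elev <- matrix(rnorm(n, truth$elev_mean[lab], truth$elev_sd[lab]), nr, nc)
  chm <- matrix(pmax(0, rnorm(n, truth$chm_mean[lab], truth$chm_sd[lab])), nr, nc)
  forest <- matrix(rbinom(n, 1, truth$forest_frac[lab]), nr, nc)
  cs <- truth$cell_size
  list(
    veg = grid_raster(matrix(as.numeric(lab), nr, nc), cs,
                      categories = truth$veg_class),
    elev = grid_raster(elev, cs),
    chm = grid_raster(chm, cs),
    landcover = grid_raster(forest + 1, cs,
                            categories = c("non_forest", "forest")),
    labels = grid_raster(matrix(as.numeric(lab), nr, nc), cs)
  )
}

#' Generative truth for a half-hourly eddy-covariance series
#'
#' Nighttime NEE follows Lloyd-Taylor respiration; daytime NEE is respiration
#' minus a rectangular-hyperbola light response. Records with friction
#' velocity below `ustar_threshold` at night have artificially attenuated
#' magnitude (emulating the low-turbulence bias the u*-filter removes); a
#' stated fraction of records is masked as gaps and a stated fraction carries
#' quality flag 2.
#'
#' @param rref Reference respiration at 15 degC (umol CO2 m-2 s-1).
#' @param e0 Lloyd-Taylor temperature sensitivity (K).
#' @param tref,t0 Reference temperatures (K).
#' @param alpha Quantum yield of the light response (umol CO2 per W m-2).
#' @param gpp_max Asymptotic GPP (umol CO2 m-2 s-1).
#' @param ustar_threshold True u* suppression threshold (m s-1).
#' @param suppression Fraction of the true flux retained for nighttime
#'   records below the u* threshold (sharp onset at the threshold).
#' @param gap_fraction Fraction of records masked as missing, in \[0, 1).
#' @param block_gaps If `TRUE`, gaps come in day-long blocks instead of
#'   missing-completely-at-random half hours.
#' @param flag2_fraction Fraction of records given quality flag 2.
#' @param noise_sd Gaussian noise SD added to NEE (umol CO2 m-2 s-1).
#' @param storage_sd SD of the synthetic storage term split off the flux.
#' @param seed Integer seed.
#' @return A `flux_truth` list.
#' @export
flux_truth <- function(rref = 3.0, e0 = 200, tref = LT_TREF_K, t0 = LT_T0_K,
                       alpha = 0.06, gpp_max = 10,
                       ustar_threshold = 0.30, suppression = 0.45,
                       gap_fraction = 0.08, block_gaps = FALSE,
                       flag2_fraction = 0.05,
                       noise_sd = 2.0, storage_sd = 0.3, seed = 1L) {
  stopifnot(gap_fraction >= 0, gap_fraction < 1, ustar_threshold > 0,
            noise_sd >= 0, storage_sd >= 0, rref > 0, e0 > 0,
            flag2_fraction >= 0, flag2_fraction < 1,
            suppression > 0, suppression <= 1)
  structure(list(rref = rref, e0 = e0, tref = tref, t0 = t0, alpha = alpha,
                 gpp_max = gpp_max, ustar_threshold = ustar_threshold,
                 suppression = suppression, gap_fraction = gap_fraction,
                 block_gaps = block_gaps, flag2_fraction = flag2_fraction,
                 noise_sd = noise_sd, storage_sd = storage_sd,
                 seed = as.integer(seed)),
            class = "flux_truth")
}

# deterministic met drivers for an austral mid-latitude site; `frac_doy` in
# [0, 365), `hour` decimal hour of day
ec_met_model <- function(doy, hour) {
  seas <- cos(2 * pi * (doy - 15) / 365)       # +1 mid-January (austral summer)
  daylen <- 12 + 3.8 * seas                    # hours of daylight (~lat 45 S)
  sunrise <- 12 - daylen / 2
  ta <- 7 + 6 * seas - 3 * cos(2 * pi * (hour - 14) / 24)
  elev_ang <- sin(pi * (hour - sunrise) / daylen)
  rg_clear <- (250 + 450 * pmax(seas, 0)) * pmax(elev_ang, 0)
  rg_clear[hour < sunrise | hour > sunrise + daylen] <- 0
  list(ta = ta, rg_clear = rg_clear, daylen = daylen)
}

#' Generate a half-hourly eddy-covariance series with known truth
#'
#' @param truth A [flux_truth()].
#' @param start Start date (first period begins at 00:00 local standard
#'   time), default `"2024-07-15"`.
#' @param days Number of days (48 records each).
#' @return A tibble with columns `timestamp`, `fc` (turbulent CO2 flux,
#'   umol m-2 s-1), `sc` (storage term), `ustar`, `qc`, `ta` (degC), `rg`
#'   (W m-2), `vpd` (hPa), `wind_dir`, `ol` (Obukhov length), `sigma_v`, and
#'   truth columns `nee_true`, `reco_true`, `gpp_true` (pre-noise,
#'   pre-suppression). The generating `flux_truth` is attached as attribute
#'   `"truth"`.
#' @export
gen_ec_series <- function(truth, start = "2024-07-15", days = 365) {
  stopifnot(inherits(truth, "flux_truth"), days >= 1)
  set.seed(truth$seed)
  n <- days * 48
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  timestamp <- t0 + (seq_len(n) - 1) * 1800
  doy <- as.numeric(format(timestamp, "%j")) +
    (as.numeric(format(timestamp, "%H")) +
       as.numeric(format(timestamp, "%M")) / 60) / 24
  hour <- as.numeric(format(timestamp, "%H")) +
    as.numeric(format(timestamp, "%M")) / 60

  met <- ec_met_model(doy, hour)
  # day-scale cloudiness and persistent synoptic temperature anomalies
  cloud_day <- runif(days, 0.35, 1)
  cloud <- rep(cloud_day, each = 48)
  rg <- met$rg_clear * cloud
  ta_anom <- as.numeric(stats::filter(rnorm(days, 0, 3 * sqrt(1 - 0.6^2)),
                                      0.6, method = "recursive"))
  ta <- met$ta + rep(ta_anom, each = 48)
  # saturation-deficit proxy, larger on warm bright afternoons
  vpd <- pmax(0, 0.5 + 0.35 * pmax(ta, 0) + 0.006 * rg +
                rnorm(n, 0, 0.8))

  reco_true <- lloyd_taylor(ta + 273.15, truth$rref, truth$e0,
                            truth$tref, truth$t0)
  gpp_true <- light_response(rg, truth$alpha, truth$gpp_max)
  nee_true <- reco_true - gpp_true

  night <- is_night(rg)
  # lognormal friction velocity; calm (sub-threshold) nights are a minority,
  # so that screening plus gaps leaves roughly three quarters of the record
  # as good-quality data, as at a windy maritime forest site
  ustar <- rlnorm(n, log(0.45), 0.45) * ifelse(night, 1, 1.3)

  nee_obs <- nee_true + rnorm(n, 0, truth$noise_sd)
  supp <- night & ustar < truth$ustar_threshold
  nee_obs[supp] <- nee_obs[supp] * truth$suppression

  sc <- rnorm(n, 0, truth$storage_sd)
  fc <- nee_obs - sc

  qc <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.8, 0.2))
  if (truth$flag2_fraction > 0) {
    qc[sample.int(n, round(truth$flag2_fraction * n))] <- 2L
  }

  gap <- rep(FALSE, n)
  n_gap <- round(truth$gap_fraction * n)
  if (n_gap > 0) {
    if (truth$block_gaps) {
      n_blocks <- max(1, round(n_gap / 48))
      starts <- sample.int(n - 48, n_blocks)
      for (s in starts) gap[s:(s + 47)] <- TRUE
    } else {
      gap[sample.int(n, n_gap)] <- TRUE
    }
  }
  fc[gap] <- NA
  sc[gap] <- NA
  ustar[gap] <- NA

  wind_dir <- (runif(n, 0, 360) + 180 * rbinom(n, 1, 0.3)) %% 360
  ol <- ifelse(night, runif(n, 10, 200), -runif(n, 10, 500))
  sigma_v <- pmax(0.1, 1.8 * ustar + rnorm(n, 0, 0.1))

  out <- tibble::tibble(
    timestamp = timestamp, fc = fc, sc = sc, ustar = ustar, qc = qc,
    ta = ta, rg = rg, vpd = vpd, wind_dir = wind_dir, ol = ol,
    sigma_v = sigma_v,
    nee_true = nee_true, reco_true = reco_true, gpp_true = gpp_true
  )
  attr(out, "truth") <- truth
  out
}

#' Planted annual NEE of a flux fixture
#'
#' Closed-form evaluation of the generating model (no noise, no suppression,
#' no gaps) summed over the series and converted to Mg CO2 ha-1 for the run
#' length.
#'
#' @param series Output of [gen_ec_series()].
#' @return NEE total in Mg CO2 ha-1 over the series span.
#' @export
planted_nee_total <- function(series) {
  sum(series$nee_true) * UMOL_HALFHOUR_TO_MG_CO2_HA
}

#' Generative truth for 8-day satellite proxy series
#'
#' GPP is proportional to SIF with a season-specific slope; RECO follows a
#' Lloyd-Taylor temperature response of land-surface temperature scaled by a
#' land-surface-water-index term; NEE = RECO - GPP. Seasonal dynamic ranges
#' (LST 292 +/- 30 K, LSWI 0.48 +/- 0.35 capped at `lswimax`) emulate the
#' dynamic range implied by the respiration-model fit quality this form is
#' expected to attain at the stated residual scale.
#'
#' @param slopes Named per-season SIF->GPP slopes (g C m-2 day-1 per SIF
#'   unit): defaults summer 18.2, spring 15.9, autumn 13.5, winter 10.4.
#' @param r0 Base respiration (g C m-2 day-1).
#' @param k Water-index sensitivity (unitless).
#' @param lswimax Maximum land-surface water index.
#' @param e0 Temperature sensitivity (K).
#' @param interval_days Observation cadence (default 8).
#' @param noise_gpp_frac GPP noise SD as a fraction of the seasonal mean
#'   signal (default 0.10).
#' @param noise_reco_sd RECO noise SD (g C m-2 day-1; default 2.80).
#' @param seed Integer seed.
#' @return A `sat_truth` list.
#' @export
sat_truth <- function(slopes = c(summer = 18.2, autumn = 13.5,
                                 winter = 10.4, spring = 15.9),
                      r0 = 2.23, k = 0.68, lswimax = 0.87, e0 = 198.31,
                      interval_days = 8, noise_gpp_frac = 0.10,
                      noise_reco_sd = 2.80, seed = 1L) {
  stopifnot(all(slopes > 0), interval_days >= 1, r0 > 0, e0 > 0,
            lswimax > -1, lswimax <= 1, noise_reco_sd >= 0)
  structure(list(slopes = slopes, r0 = r0, k = k, lswimax = lswimax, e0 = e0,
                 interval_days = interval_days,
                 noise_gpp_frac = noise_gpp_frac,
                 noise_reco_sd = noise_reco_sd, seed = as.integer(seed)),
            class = "sat_truth")
}

#' Generate 8-day satellite proxy samples with known truth
#'
#' @param truth A [sat_truth()].
#' @param years Number of calendar years, starting `start_year`.
#' @param n_pixels Number of pixels.
#' @param start_year First year (default 2013).
#' @return Tibble with `date`, `pixel`, `season`, `sif`, `lst` (K), `lswi`,
#'   `gpp`, `reco`, `nee` (all fluxes g C m-2 day-1) plus noiseless truth
#'   columns `gpp_true`, `reco_true`. Truth attached as attribute `"truth"`.
#' @export
gen_satellite_series <- function(truth, years = 8, n_pixels = 25,
                                 start_year = 2013) {
  stopifnot(inherits(truth, "sat_truth"), years >= 1, n_pixels >= 1)
  set.seed(truth$seed)
  doys <- seq(1, 365, by = truth$interval_days)
  dates <- as.Date(unlist(lapply(seq_len(years), function(i) {
    as.Date(doys - 1, origin = sprintf("%d-01-01", start_year + i - 1))
  })), origin = "1970-01-01")
  nt <- length(dates)
  season <- assign_season(dates)
  doy <- as.numeric(format(dates, "%j"))
  seas <- cos(2 * pi * (doy - 15) / 365)

  pix_t <- rnorm(n_pixels, 0, 6)      # pixel-level LST offset (K)
  pix_w <- rnorm(n_pixels, 0, 0.08)   # pixel-level wetness offset

  out <- purrr::map_dfr(seq_len(n_pixels), function(p) {
    sif <- pmax(0, 0.55 + 0.45 * seas + rnorm(nt, 0, 0.08))
    gpp_true <- unname(truth$slopes[season]) * sif
    # proportional noise: SD is a stated fraction of the signal
    gpp <- gpp_true + rnorm(nt, 0, truth$noise_gpp_frac * gpp_true)
    lst <- 292 + 30 * seas + pix_t[p] + rnorm(nt, 0, 4)
    lswi <- pmin(truth$lswimax,
                 0.48 + 0.35 * seas + pix_w[p] + rnorm(nt, 0, 0.05))
    w <- (1 + truth$k * lswi) / (1 + truth$k * truth$lswimax)
    reco_true <- truth$r0 * w *
      exp(truth$e0 * (1 / (LT_TREF_K - LT_T0_K) - 1 / (lst - LT_T0_K)))
    reco <- reco_true + rnorm(nt, 0, truth$noise_reco_sd)
    tibble::tibble(date = dates, pixel = p, season = season,
                   sif = sif, lst = lst, lswi = lswi,
                   gpp = gpp, reco = reco, nee = reco - gpp,
                   gpp_true = gpp_true, reco_true = reco_true)
  })
  attr(out, "truth") <- truth
  out
}

#' Write a truth ledger as YAML
#'
#' Records the generating parameters of a fixture alongside the data it
#' produced, for provenance.
#'
#' @param truth A truth object (`landscape_truth`, `flux_truth`,
#'   `sat_truth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(c(list(class = class(truth)[1]), unclass(truth)), path)
  invisible(path)
}
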