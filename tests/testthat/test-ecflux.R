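test_that("quality screening marks but never alters values", {
  s <- tibble::tibble(
    timestamp = as.POSIXct("2024-01-01", tz = "UTC") + (0:5) * 1800,
    fc = c(-5, 3, 120, 2, -1, 4), qc = c(0L, 0L, 1L, 2L, 1L, 2L),
    sc = rep(0, 6))
  out <- qc_screen(s)
  expect_equal(sum(out$quality_state == "measured"), 3)  # qc2 x2 + range x1
  expect_equal(out$fc, s$fc)  # values retained for audit
  expect_equal(out$screen_reason[3], "range")
  expect_equal(out$screen_reason[4], "qc_flag")

  flags <- tibble::tibble(timestamp = s$timestamp, fc = rep(1, 6),
                          qc = c(0L, 0L, 1L, 2L, 1L, 2L), sc = rep(0, 6))
  expect_equal(sum(qc_screen(flags)$quality_state == "measured"), 4)

  clean <- tibble::tibble(timestamp = s$timestamp, fc = rep(1, 6),
                          qc = rep(0L, 6), sc = rep(0, 6))
  expect_true(all(qc_screen(clean)$quality_state == "measured"))
  bad <- clean; bad$qc[1] <- 7L
  expect_error(qc_screen(bad), "flags")
})

test_that("storage addition is linear and warns when absent", {
  s <- tibble::tibble(timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
                        (0:1) * 1800,
                      fc = c(-5, 2), sc = c(1, 0.5), qc = c(0L, 0L))
  out <- add_storage(s)
  expect_equal(out$nee, c(-4, 2.5))
  expect_equal(sum(out$nee), sum(s$fc) + sum(s$sc))
  s2 <- s[, c("timestamp", "fc", "qc")]
  expect_warning(out2 <- add_storage(s2), "storage")
  expect_equal(out2$nee, s2$fc)
})

test_that("u* filtering removes exactly the calm nighttime records", {
  ec <- gen_ec_series(flux_truth(seed = 14), days = 30) |>
    add_storage() |> qc_screen()
  f0 <- apply_ustar_filter(ec, 0)
  expect_identical(f0$quality_state, ec$quality_state)
  fin <- apply_ustar_filter(ec, Inf)
  night_meas <- is_night(ec$rg) & ec$quality_state == "measured" &
    !is.na(ec$ustar)
  expect_true(all(fin$quality_state[night_meas] == "screened_out"))
  thr <- 0.3
  fm <- apply_ustar_filter(ec, thr)
  brute <- sum(night_meas & ec$ustar < thr, na.rm = TRUE)
  expect_equal(sum(fm$screen_reason == "ustar", na.rm = TRUE), brute)
})

test_that("aggregation matches the dimensional-analysis oracle", {
  wk <- make_flat_series(336)
  expect_equal(aggregate_flux(wk, "week")$nee, 0.266172, tolerance = 1e-4)
  yr <- make_flat_series(365 * 48)
  expect_equal(aggregate_flux(yr, "year")$nee, 13.879, tolerance = 1e-4)
  zero <- make_flat_series(336, nee = 0)
  expect_equal(aggregate_flux(zero, "week")$nee, 0)
  gap <- make_flat_series(10); gap$nee[3] <- NA
  expect_error(aggregate_flux(gap, "week"), "gaps")
})

test_that("weekly sums over a year equal the annual sum", {
  ec <- gen_ec_series(flux_truth(noise_sd = 0.5, gap_fraction = 0,
                                 flag2_fraction = 0, suppression = 1,
                                 seed = 4), days = 365) |> add_storage()
  wk <- aggregate_flux(ec, "week")
  yr <- aggregate_flux(ec, "year")
  expect_equal(sum(wk$nee), sum(yr$nee), tolerance = 1e-10)
  expect_equal(sum(wk$n), 365 * 48)
})

test_that("uncertainty propagation adds variances", {
  expect_equal(propagate(c(3, 4)), 5)
  expect_equal(propagate(7), 7)
  expect_equal(propagate(c(0, 0, 0)), 0)
  expect_equal(propagate(c(4, 3)), propagate(c(3, 4)))  # order-invariant
  expect_error(propagate(c(-1, 2)), "negative")
  b <- uncertainty_budget(0.1, 0.05, 0.02)
  expect_equal(b$sigma_total^2,
               b$sigma_random^2 + b$sigma_ustar^2 + b$sigma_gapfill^2)
})

test_that("u* threshold sits at the lowest class when flux is independent
           of turbulence, and the bootstrap size is honoured", {
  set.seed(9)
  n <- 4000
  s <- tibble::tibble(
    timestamp = as.POSIXct("2024-01-01", tz = "UTC") + (0:(n - 1)) * 1800,
    nee = rnorm(n, 3, 0.2), ustar = runif(n, 0.05, 0.8),
    ta = rnorm(n, 5, 4), rg = 0, qc = 0L, fc = rnorm(n, 3, 0.2), sc = 0,
    vpd = 1)
  s <- add_storage(qc_screen(s))
  res <- ustar_threshold(s, n_boot = 100, seed = 2)
  # plateau satisfied immediately: threshold within the lowest u* class
  expect_lt(res$threshold, quantile(s$ustar, 0.08))
  expect_length(res$boot, 100)
  expect_error(ustar_threshold(s[1:50, ], seed = 1), "insufficient")
})

test_that("u* threshold recovers the planted suppression onset", {
  ec <- gen_ec_series(flux_truth(seed = 19), days = 365) |>
    add_storage() |> qc_screen()
  res <- ustar_threshold(ec, n_boot = 20, seed = 3)
  expect_gt(res$threshold, 0.25)
  expect_lt(res$threshold, 0.35)
})

test_that("gap-filling reproduces a deterministic flux surface and is
           seed-stable", {
  ec <- gen_ec_series(flux_truth(noise_sd = 0, gap_fraction = 0.25,
                                 flag2_fraction = 0, suppression = 1,
                                 seed = 23), days = 90) |>
    add_storage() |> qc_screen()
  gf <- gapfill(ec, seed = 2)
  filled <- gf$quality_state == "gap_filled"
  expect_gt(sum(filled), 0)
  r2 <- 1 - sum((gf$nee[filled] - gf$nee_true[filled])^2) /
    sum((gf$nee_true[filled] - mean(gf$nee_true[filled]))^2)
  expect_gte(r2, 0.95)
  gf2 <- gapfill(ec, seed = 2)
  expect_identical(gf$nee, gf2$nee)

  # no gaps: values unchanged, diagnostics still computed
  full <- gen_ec_series(flux_truth(gap_fraction = 0, flag2_fraction = 0,
                                   seed = 3), days = 30) |>
    add_storage() |> qc_screen()
  gf3 <- gapfill(full, seed = 1)
  expect_equal(gf3$nee, full$nee)
  expect_true(is.finite(attr(gf3, "oob_r2")))
  expect_error(gapfill(dplyr::mutate(full, vpd = NA_real_), seed = 1),
               "vpd")
})

test_that("random error recovers planted iid noise and degrades gracefully", {
  ec <- gen_ec_series(flux_truth(noise_sd = 2.0, gap_fraction = 0,
                                 flag2_fraction = 0, seed = 31),
                      days = 90) |> add_storage() |> qc_screen()
  sig <- suppressWarnings(random_error(ec))
  expect_lt(abs(median(sig, na.rm = TRUE) - 2.0) / 2.0, 0.2)

  # two identical days -> zero error
  one_day <- gen_ec_series(flux_truth(noise_sd = 0, gap_fraction = 0,
                                      flag2_fraction = 0, suppression = 1,
                                      seed = 2), days = 1)
  two <- dplyr::bind_rows(one_day,
                          dplyr::mutate(one_day,
                                        timestamp = timestamp + 86400)) |>
    add_storage() |> qc_screen()
  sig2 <- suppressWarnings(random_error(two))
  expect_true(all(sig2[!is.na(sig2)] < 1e-9))

  # no similar pairs anywhere -> defaults with warning
  n <- 96
  wild <- tibble::tibble(
    timestamp = as.POSIXct("2024-01-01", tz = "UTC") + (0:(n - 1)) * 1800,
    fc = rnorm(n), sc = 0, qc = 0L, ustar = 0.4,
    ta = seq(0, 500, length.out = n), rg = seq(0, 5000, length.out = n),
    vpd = seq(0, 300, length.out = n))
  wild <- add_storage(qc_screen(wild))
  expect_warning(random_error(wild), "no similar pairs")
})

test_that("partitioning honours the NEE identity and nocturnal conventions", {
  ec <- gen_ec_series(flux_truth(seed = 37), days = 120) |>
    add_storage() |> qc_screen()
  gf <- gapfill(apply_ustar_filter(ec, 0.3), seed = 1)
  pt <- partition_nee(gf)
  night <- is_night(pt$rg)
  expect_true(all(pt$gpp[night] == 0))
  expect_equal(pt$nee, pt$reco - pt$gpp, tolerance = 1e-10)
  expect_true(attr(pt, "e0") > 30 && attr(pt, "e0") < 450)
})

test_that("bootstrap uncertainty responds to planted noise", {
  ec_lo <- gen_ec_series(flux_truth(noise_sd = 1, seed = 41), days = 120) |>
    add_storage() |> qc_screen()
  ec_hi <- gen_ec_series(flux_truth(noise_sd = 4, seed = 41), days = 120) |>
    add_storage() |> qc_screen()
  ur_lo <- ustar_threshold(ec_lo, n_boot = 10, seed = 1)
  ur_hi <- ustar_threshold(ec_hi, n_boot = 10, seed = 1)
  bu_lo <- bootstrap_uncertainty(ec_lo, ur_lo, n_boot = 20, n_trees = 10,
                                 seed = 2)
  bu_hi <- bootstrap_uncertainty(ec_hi, ur_hi, n_boot = 20, n_trees = 10,
                                 seed = 2)
  expect_equal(nrow(bu_lo$aggregates_gapfill), 20)  # retained for audit
  expect_gt(bu_hi$sigma_gapfill[1], bu_lo$sigma_gapfill[1])
  expect_error(bootstrap_uncertainty(ec_lo, ur_lo, n_boot = 1), "n_boot")
})
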