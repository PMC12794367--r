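test_that("seasons follow the austral month-wise convention", {
  expect_equal(assign_season(as.Date("2024-01-15")), "summer")
  expect_equal(assign_season(as.Date("2024-07-15")), "winter")
  expect_equal(assign_season(as.Date("2024-04-01")), "autumn")
  expect_equal(assign_season(as.Date("2024-10-31")), "spring")
  # boundaries map month-wise: all of March is autumn
  expect_equal(assign_season(as.Date(c("2024-03-01", "2024-03-31"))),
               c("autumn", "autumn"))
})

test_that("origin-constrained SIF slopes equal the closed form", {
  set.seed(5)
  d <- tibble::tibble(season = rep("summer", 30),
                      sif = runif(30, 0.1, 1))
  d$gpp <- 18.2 * d$sif
  m <- fit_sif_gpp(d)
  expect_equal(m$seasons$slope, 18.2, tolerance = 1e-12)
  expect_equal(m$seasons$r_squared, 1)
  # closed-form oracle on noisy data
  d2 <- d; d2$gpp <- d2$gpp + rnorm(30, 0, 1)
  m2 <- fit_sif_gpp(d2)
  expect_equal(m2$seasons$slope, sum(d2$sif * d2$gpp) / sum(d2$sif^2),
               tolerance = 1e-12)
  d0 <- tibble::tibble(season = "winter", sif = rep(0, 5), gpp = rep(0, 5))
  expect_error(fit_sif_gpp(d0), "all-zero SIF")
  expect_error(fit_sif_gpp(d[1:2, ]), "too few")
})

test_that("GPP prediction is proportional and clamps negative SIF", {
  m <- fit_sif_gpp(tibble::tibble(season = "summer", sif = c(1, 2, 3),
                                  gpp = c(10, 20, 30)))
  expect_equal(predict_gpp(m, 0, "summer"), 0)
  expect_equal(predict_gpp(m, 2, "summer"), 2 * predict_gpp(m, 1, "summer"))
  expect_equal(predict_gpp(m, -0.5, "summer"), 0)
  expect_error(predict_gpp(m, 1, "monsoon"), "unknown season")
})

test_that("respiration model evaluates its closed form", {
  m <- reco_model(r0 = 2.23, k = 0.68, lswimax = 0.87, e0 = 198.31)
  # at the reference temperature and maximum wetness the flux is R0
  expect_equal(predict_reco(m, forestcarbon:::LT_TREF_K, 0.87), 2.23,
               tolerance = 1e-12, ignore_attr = TRUE)
  # strictly increasing in LST at fixed LSWI
  lst <- seq(270, 310, 2)
  expect_true(all(diff(predict_reco(m, lst, rep(0.5, length(lst)))) > 0))
  # brute-force formula evaluation
  w <- (1 + 0.68 * 0.3) / (1 + 0.68 * 0.87)
  expect_equal(
    predict_reco(m, 290, 0.3),
    2.23 * w * exp(198.31 * (1 / (288.15 - 227.13) - 1 / (290 - 227.13))),
    tolerance = 1e-12, ignore_attr = TRUE)
  # LST below T0 -> missing, counted
  out <- predict_reco(m, c(290, 200), c(0.5, 0.5))
  expect_true(is.na(out[2]))
  expect_equal(attr(out, "n_invalid"), 1)
})

test_that("respiration fit recovers noiseless parameters exactly", {
  ss <- gen_satellite_series(sat_truth(noise_gpp_frac = 0, noise_reco_sd = 0,
                                       seed = 13), years = 2, n_pixels = 2)
  m <- fit_reco(ss)
  expect_equal(m$r0, 2.23, tolerance = 0.01)
  expect_equal(m$k, 0.68, tolerance = 0.01)
  expect_equal(m$lswimax, 0.87, tolerance = 0.01)
  expect_equal(m$e0, 198.31, tolerance = 0.01 * 198.31)
  expect_error(fit_reco(ss[1:5, ]), "at least 10")
})

test_that("NEE maps are the RECO - GPP difference with missing propagation", {
  gpp <- grid_raster(matrix(c(8, 0, NA, 2), 2, 2))
  reco <- grid_raster(matrix(c(5, 5, 5, NA), 2, 2))
  nee <- compute_nee(gpp, reco)
  expect_equal(nee$values[1, 1], -3)
  expect_equal(nee$values[2, 1], 5)
  expect_true(all(is.na(nee$values[c(3, 4)])))
  ok <- !is.na(nee$values)
  expect_equal(mean(nee$values[ok]),
               mean(reco$values[ok]) - mean(gpp$values[ok]))
  off <- grid_raster(matrix(1, 3, 3))
  expect_error(compute_nee(gpp, off), "co-registered")
})

test_that("downscaling interpolates and conserves under predictor weighting", {
  coarse <- grid_raster(matrix(5, 3, 3), cell_size = 90)
  target <- grid_raster(matrix(0, 9, 9), cell_size = 30)
  fine <- downscale(coarse, target)
  expect_true(all(abs(fine$values - 5) < 1e-9))

  set.seed(8)
  coarse2 <- grid_raster(matrix(runif(9, 1, 10), 3, 3), cell_size = 90)
  pred <- grid_raster(matrix(runif(81, 0.5, 2), 9, 9), cell_size = 30)
  cons <- downscale(coarse2, target, predictor = pred)
  for (i in 1:3) for (j in 1:3) {
    block <- cons$values[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]
    expect_equal(mean(block), coarse2$values[i, j], tolerance = 1e-10)
  }
  # bilinear interpolation reproduces coarse values at coarse cell centres
  target2 <- grid_raster(matrix(0, 3, 3), cell_size = 90)
  same <- downscale(coarse2, target2)
  expect_equal(same$values, coarse2$values, tolerance = 1e-9)
  far <- grid_raster(matrix(0, 3, 3), cell_size = 30, xll = 1e6, yll = 1e6)
  expect_error(downscale(coarse2, far), "overlap")
})

test_that("validation is exact on identical series and flags planted spikes", {
  x <- sin(seq(0, 6 * pi, length.out = 200)) * 5 + 6
  v <- validate_fluxes(x, x)
  expect_equal(v$beta, 1)
  expect_equal(v$r_squared, 1)
  expect_equal(v$rmse, 0)
  expect_equal(v$bias, 0)
  expect_equal(v$outliers_removed, 0)

  y <- x
  y[100] <- x[100] + 60  # >> 10 scaled MADs of the difference series
  v2 <- validate_fluxes(y, x)
  expect_equal(v2$outliers_removed, 1)
  expect_equal(v2$rmse, 0, tolerance = 1e-10)

  set.seed(21)
  obs <- rep(seq(1, 15, length.out = 46), 8)
  noise_sd <- 1.0
  v3 <- validate_fluxes(obs, obs + rnorm(368, 0, noise_sd))
  expect_lt(abs(v3$rmse - noise_sd) / noise_sd, 0.15)
  expect_error(validate_fluxes(x[1:2], x[1:2]), "fewer than 3")
})

test_that("hampel filter flags rolling-median outliers", {
  x <- c(rep(1, 10), 50, rep(1, 10)) + seq(0, 0.2, length.out = 21)
  out <- hampel_outliers(x)
  expect_true(out[11])
  expect_equal(sum(out), 1)
})

test_that("the extrapolation factor is an exact ratio of medians", {
  expect_equal(compute_pext(c(-5, -5, -5), c(-5, -5, -5))$value, 1)
  expect_equal(compute_pext(c(-6, -6), c(-4, -4))$value, 1.5)
  # sort-based oracle, odd and even n
  set.seed(3)
  for (n in c(7, 8)) {
    a <- rnorm(n, -5); b <- rnorm(n, -4)
    p <- compute_pext(a, b)
    med <- function(v) {
      sv <- sort(v)
      if (length(sv) %% 2 == 1) sv[(length(sv) + 1) / 2]
      else mean(sv[length(sv) / 2 + 0:1])
    }
    expect_equal(p$value, med(a) / med(b), tolerance = 1e-12)
  }
  # invariance under common positive rescaling
  a <- rnorm(50, -6); b <- rnorm(50, -4)
  expect_equal(compute_pext(3.7 * a, 3.7 * b)$value,
               compute_pext(a, b)$value, tolerance = 1e-12)
  expect_error(compute_pext(numeric(0), b), "non-empty")
  expect_error(compute_pext(a, c(-1, 1)), "zero")
})

test_that("a footprint that subsamples the cluster gives a factor near 1", {
  set.seed(17)
  efc <- rnorm(2e4, -5, 2)
  fp <- sample(efc, 1e4)
  expect_equal(compute_pext(efc, fp)$value, 1, tolerance = 0.02)
})
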