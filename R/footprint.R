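# Two-dimensional flux-footprint parameterisation: a crosswind-integrated
# footprint in scaled upwind distance, scaled by a Gaussian crosswind
# spread, with stability entering through the Monin-Obukhov correction of
# the wind profile. Per-record footprints are rotated to the wind direction
# and averaged into a climatology.

FFP_A <- 1.4524
FFP_B <- -1.9914
FFP_C <- 1.4622
FFP_D <- 0.1359
FFP_AC <- 2.17
FFP_BC <- 1.66
FFP_CC <- 20.0

ffp_psi <- function(zm, ol) {
  if (ol > 0) {
    -5.3 * zm / ol
  } else {
    xx <- (1 - 19 * zm / ol)^0.25
    log((1 + xx^2) / 2) + 2 * log((1 + xx) / 2) - 2 * atan(xx) + pi / 2
  }
}

ffp_valid <- function(zm, z0, ol, ustar, h) {
  is.finite(ol) && ol != 0 && zm / ol >= -15.5 && ustar > 0.1 &&
    zm > z0 && zm < h && h > 10
}

# crosswind-integrated footprint f_ci(x) [m-1] and spread sigma_y(x) [m]
ffp_ci <- function(x, zm, z0, ol, ustar, sigma_v, h) {
  psi <- ffp_psi(zm, ol)
  denom <- log(zm / z0) - psi
  if (denom <= 0) return(NULL)
  xstar <- x / zm * (1 - zm / h) / denom
  fstar <- rep(0, length(x))
  okx <- xstar > FFP_D
  fstar[okx] <- FFP_A * (xstar[okx] - FFP_D)^FFP_B *
    exp(-FFP_C / (xstar[okx] - FFP_D))
  f_ci <- fstar / zm * (1 - zm / h) / denom
  sigystar <- FFP_AC * sqrt(FFP_BC * xstar^2 / (1 + FFP_CC * xstar))
  ps1 <- min(1, 1e-5 * abs(zm / ol)^(-1) + if (ol <= 0) 0.80 else 0.55)
  sigy <- sigystar / ps1 * zm * sigma_v / ustar
  list(f_ci = f_ci, sigy = sigy, xstar = xstar)
}

# one record's 2D footprint on tower-centred grid (matrices gx, gy east/north)
ffp_record <- function(gx, gy, wind_dir, zm, z0, ol, ustar, sigma_v, h) {
  th <- wind_dir * pi / 180
  xa <- gx * sin(th) + gy * cos(th)     # upwind (along-wind) distance
  yc <- -gx * cos(th) + gy * sin(th)    # crosswind distance
  ci <- ffp_ci(pmax(as.vector(xa), 0), zm, z0, ol, ustar, sigma_v, h)
  if (is.null(ci)) return(NULL)
  f <- ci$f_ci * ifelse(ci$sigy > 0,
                        dnorm(as.vector(yc), 0, ci$sigy), 0)
  f[!is.finite(f)] <- 0
  matrix(f, nrow(gx), ncol(gx))
}

#' Flux-footprint climatology
#'
#' Evaluates the two-dimensional footprint parameterisation for every valid
#' record (rotated to its wind direction) on a tower-centred grid and
#' averages them into a source-weight climatology. Records outside the
#' parameterisation's validity envelope (strongly convective `zm/L <
#' -15.5`, `u* <= 0.1`, geometry violations) are skipped and counted.
#'
#' @param series Flux tibble with `wind_dir` (deg), `ustar`, `ol` (Obukhov
#'   length, m), `sigma_v` (crosswind velocity SD, m s-1).
#' @param zm Measurement height above displacement (m).
#' @param z0 Roughness length (m).
#' @param h Boundary-layer height (m), default 1500.
#' @param grid List with `xmin`, `xmax`, `ymin`, `ymax`, `res` (m) defining
#'   the tower-centred grid (east/north).
#' @return A `footprint_grid`: `density` `grid_raster` (m-2, tower at the
#'   grid centre origin), `n_used`, `n_skipped`.
#' @export
footprint_climatology <- function(series, zm, z0, h = 1500,
                                  grid = list(xmin = -300, xmax = 300,
                                              ymin = -300, ymax = 300,
                                              res = 10)) {
  stopifnot(zm > z0)
  xs <- seq(grid$xmin + grid$res / 2, grid$xmax - grid$res / 2, grid$res)
  ys <- seq(grid$ymax - grid$res / 2, grid$ymin + grid$res / 2, -grid$res)
  gx <- matrix(rep(xs, each = length(ys)), length(ys), length(xs))
  gy <- matrix(rep(ys, length(xs)), length(ys), length(xs))
  acc <- matrix(0, length(ys), length(xs))
  used <- 0L; skipped <- 0L
  for (i in seq_len(nrow(series))) {
    rec <- series[i, ]
    if (anyNA(c(rec$wind_dir, rec$ustar, rec$ol, rec$sigma_v)) ||
        !ffp_valid(zm, z0, rec$ol, rec$ustar, h)) {
      skipped <- skipped + 1L
      next
    }
    f <- ffp_record(gx, gy, rec$wind_dir, zm, z0, rec$ol, rec$ustar,
                    rec$sigma_v, h)
    if (is.null(f)) { skipped <- skipped + 1L; next }
    acc <- acc + f
    used <- used + 1L
  }
  if (used == 0) stop("no records inside the footprint validity envelope")
  dens <- grid_raster(acc / used, cell_size = grid$res,
                      xll = grid$xmin, yll = grid$ymin, crs = "local")
  structure(list(density = dens, n_used = used, n_skipped = skipped,
                 zm = zm, z0 = z0, h = h),
            class = "footprint_grid")
}

#' @export
print.footprint_grid <- function(x, ...) {
  tot <- sum(x$density$values) * x$density$cell_size^2
  cat(sprintf("<footprint_grid> %d x %d cells at %g m; integral %.3f; %d records (%d skipped)\n",
              nrow(x$density$values), ncol(x$density$values),
              x$density$cell_size, tot, x$n_used, x$n_skipped))
  invisible(x)
}

#' Source area of a footprint
#'
#' Smallest-area cell set containing fraction `r` of the footprint's total
#' density on the grid.
#'
#' @param footprint A `footprint_grid`.
#' @param r Source-area fraction in (0, 1), default 0.70.
#' @return List with `area_ha`, `mask` (`grid_raster` of 0/1), `r`.
#' @export
source_area <- function(footprint, r = 0.70) {
  if (r <= 0 || r >= 1) stop("r must be in (0, 1)")
  v <- as.vector(footprint$density$values)
  total <- sum(v)
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  ncells <- which(cum >= r * total)[1]
  mask <- rep(0, length(v))
  mask[ord[seq_len(ncells)]] <- 1
  cell_area <- footprint$density$cell_size^2
  m <- footprint$density
  m$values <- matrix(mask, nrow(m$values), ncol(m$values))
  list(area_ha = ncells * cell_area / 1e4, mask = m, r = r)
}

#' Exclude records with weak footprint overlap of a target area
#'
#' Computes each record's footprint fraction inside a target polygon and
#' marks records below `min_inside` as screened-out.
#'
#' @param series Flux tibble with footprint inputs (see
#'   [footprint_climatology()]).
#' @param zm,z0,h,grid Footprint configuration.
#' @param polygon Two-column matrix of polygon vertices (east/north, m,
#'   tower at origin).
#' @param min_inside Minimum within-polygon footprint fraction (default
#'   0.70).
#' @return The series with updated quality state; records that could not be
#'   evaluated are left untouched. The per-record fraction is returned in a
#'   `footprint_inside` column.
#' @export
footprint_exclusion <- function(series, zm, z0, polygon, h = 1500,
                                grid = list(xmin = -300, xmax = 300,
                                            ymin = -300, ymax = 300,
                                            res = 10),
                                min_inside = 0.70) {
  if (!is.matrix(polygon) || nrow(polygon) < 3) stop("invalid polygon")
  series <- ensure_quality_state(series)
  xs <- seq(grid$xmin + grid$res / 2, grid$xmax - grid$res / 2, grid$res)
  ys <- seq(grid$ymax - grid$res / 2, grid$ymin + grid$res / 2, -grid$res)
  gx <- matrix(rep(xs, each = length(ys)), length(ys), length(xs))
  gy <- matrix(rep(ys, length(xs)), length(ys), length(xs))
  inside <- matrix(pracma::inpolygon(as.vector(gx), as.vector(gy),
                                     polygon[, 1], polygon[, 2]),
                   length(ys), length(xs))
  frac <- rep(NA_real_, nrow(series))
  for (i in seq_len(nrow(series))) {
    rec <- series[i, ]
    if (anyNA(c(rec$wind_dir, rec$ustar, rec$ol, rec$sigma_v)) ||
        !ffp_valid(zm, z0, rec$ol, rec$ustar, h)) next
    f <- ffp_record(gx, gy, rec$wind_dir, zm, z0, rec$ol, rec$ustar,
                    rec$sigma_v, h)
    if (is.null(f) || sum(f) == 0) next
    frac[i] <- sum(f[inside]) / sum(f)
  }
  hit <- !is.na(frac) & frac < min_inside & series$quality_state == "measured"
  series$quality_state[hit] <- "screened_out"
  series$screen_reason[hit] <- "footprint"
  series$footprint_inside <- frac
  series
}

#' Plot a footprint climatology
#'
#' @param object A `footprint_grid`.
#' @param r Contour fractions to outline (default 0.7).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.footprint_grid <- function(object, r = 0.7, ...) {
  df <- as_tibble.grid_raster(object$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(m^-2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "East of tower (m)", y = "North of tower (m)")
}
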