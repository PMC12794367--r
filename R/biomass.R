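# Canopy-height based aboveground biomass and carbon density baselines.
# AGBD (Mg ha-1) follows a power-law allometry of top-of-canopy height,
# applied only where the canopy reaches a minimum height; the carbon density
# is a fixed fraction of biomass.

#' Allometry parameters for height-to-biomass conversion
#'
#' Power-law allometry \eqn{AGBD = a \cdot CHM^{b}} (Mg ha-1) for pixels with
#' canopy height at or above `h_min`, with a biomass-to-carbon conversion
#' fraction `cf`.
#'
#' @param a Coefficient (default 1.4535).
#' @param b Exponent (default 1.5546).
#' @param h_min Minimum height for biomass estimation (m, default 4).
#' @param cf Carbon fraction of dry biomass (default 0.47).
#' @return An `allometry_params` list.
#' @export
allometry_params <- function(a = 1.4535, b = 1.5546, h_min = 4, cf = 0.47) {
  stopifnot(a > 0, b > 0, h_min >= 0, cf > 0, cf < 1)
  structure(list(a = a, b = b, h_min = h_min, cf = cf),
            class = "allometry_params")
}

#' Aboveground biomass density from canopy height
#'
#' @param chm Canopy-height `grid_raster` (m) or numeric vector.
#' @param params An [allometry_params()].
#' @return AGBD (Mg ha-1) of the same shape; cells below `h_min` and missing
#'   cells are `NA`.
#' @export
agbd_from_chm <- function(chm, params = allometry_params()) {
  f <- function(h) {
    if (any(h < 0, na.rm = TRUE)) stop("negative canopy heights")
    out <- params$a * h^params$b
    out[!is.na(h) & h < params$h_min] <- NA
    out
  }
  if (inherits(chm, "grid_raster")) {
    out <- chm
    out$values <- matrix(f(as.vector(chm$values)), nrow(chm$values),
                         ncol(chm$values))
    out
  } else f(chm)
}

#' Aboveground carbon density from biomass density
#'
#' @param agbd AGBD `grid_raster` (Mg ha-1) or numeric vector.
#' @param params An [allometry_params()]; only `cf` is used.
#' @return AGCD (Mg C ha-1).
#' @export
agcd_from_agbd <- function(agbd, params = allometry_params()) {
  f <- function(x) {
    if (any(x < 0, na.rm = TRUE)) stop("negative biomass values")
    x * params$cf
  }
  if (inherits(agbd, "grid_raster")) {
    out <- agbd
    out$values <- f(agbd$values)
    out
  } else f(agbd)
}

#' Resample a canopy-height raster to a coarser grid
#'
#' Block mean of valid cells; a block that is entirely missing stays
#' missing. The target cell size must be an integer multiple of the source
#' cell size.
#'
#' @param chm Fine `grid_raster`.
#' @param target_cell Target cell size (m).
#' @return Coarser `grid_raster`.
#' @export
resample_chm <- function(chm, target_cell) {
  factor <- target_cell / chm$cell_size
  if (abs(factor - round(factor)) > 1e-9) {
    stop("target cell size must be an integer multiple of the source cell")
  }
  aggregate_raster(chm, round(factor), fun = "mean")
}

six_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty group")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(min = min(x), q1 = q[1], median = q[2], mean = mean(x),
                 q3 = q[3], max = max(x))
}

#' Descriptive statistics of canopy height and biomass
#'
#' Six statistics (min, 1st quartile, median, mean, 3rd quartile, max) per
#' variable and group. Height statistics use all valid cells; biomass
#' statistics are restricted to cells at or above the allometry's minimum
#' height, mirroring how biomass is defined.
#'
#' @param chm Canopy-height `grid_raster` (m).
#' @param agbd AGBD `grid_raster` (Mg ha-1), co-registered with `chm`
#'   (typically [agbd_from_chm()] output).
#' @param grouping Optional co-registered `grid_raster` of group codes (e.g.
#'   data source); `NULL` summarises everything as one `"general"` group.
#' @param params The [allometry_params()] used (for the height filter).
#' @return Tibble with `group`, `variable` (`"chm"`/`"agbd"`), and the six
#'   statistics; quantiles use linear interpolation between order
#'   statistics.
#' @export
summarize_structure <- function(chm, agbd, grouping = NULL,
                                params = allometry_params()) {
  stopifnot(gr_same_grid(chm, agbd))
  h <- as.vector(chm$values)
  b <- as.vector(agbd$values)
  grp <- if (is.null(grouping)) rep("general", length(h)) else {
    stopifnot(gr_same_grid(chm, grouping))
    g <- as.vector(grouping$values)
    if (!is.null(grouping$categories)) grouping$categories[g] else as.character(g)
  }
  groups <- unique(grp[!is.na(grp)])
  purrr::map_dfr(groups, function(g) {
    sel <- !is.na(grp) & grp == g
    dplyr::bind_rows(
      dplyr::mutate(six_stats(h[sel]), group = g, variable = "chm",
                    .before = 1),
      dplyr::mutate(six_stats(b[sel & !is.na(h) & h >= params$h_min]),
                    group = g, variable = "agbd", .before = 1)
    )
  })
}
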