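# Eco-functional cluster maps: classify raster stacks against a fitted
# k-prototypes model, mask to forest, and group contiguous labelled area into
# administrative constellations.

#' Classify a raster stack into eco-functional clusters
#'
#' Each valid cell is assigned to the nearest prototype of a fitted
#' [fit_kprototypes()] model under the model's mixed dissimilarity (using the
#' model's standardization); missing cells propagate.
#'
#' @param model A `kprototypes` model.
#' @param stack Named list of co-registered `grid_raster`s; names must cover
#'   the model's `numeric_cols` and `cat_cols` (categorical rasters carry a
#'   `categories` lookup).
#' @return An `efc_map`: list with `labels` (`grid_raster` of 1..k),
#'   `areas` (tibble of per-label area in ha), `constellations` (`NULL`
#'   until [group_constellations()] is applied).
#' @export
classify_raster <- function(model, stack) {
  needed <- c(model$numeric_cols, model$cat_cols)
  if (!all(needed %in% names(stack))) {
    stop("stack is missing fields: ",
         paste(setdiff(needed, names(stack)), collapse = ", "))
  }
  ref <- stack[[needed[1]]]
  for (nm in needed) {
    if (!gr_same_grid(ref, stack[[nm]])) stop("rasters are not co-registered")
  }
  num <- vapply(model$numeric_cols, function(nm) as.vector(stack[[nm]]$values),
                numeric(length(ref$values)))
  num <- matrix(num, ncol = length(model$numeric_cols))
  catm <- NULL
  if (length(model$cat_cols)) {
    catm <- vapply(model$cat_cols, function(nm) {
      r <- stack[[nm]]
      if (!is.null(r$categories)) r$categories[as.vector(r$values)]
      else as.character(as.vector(r$values))
    }, character(length(ref$values)))
    catm <- matrix(catm, ncol = length(model$cat_cols))
  }
  valid <- rowSums(is.na(num)) == 0
  if (!is.null(catm)) valid <- valid & rowSums(is.na(catm)) == 0

  lab <- rep(NA_real_, length(ref$values))
  if (any(valid)) {
    znum <- sweep(sweep(num[valid, , drop = FALSE], 2, model$scale$mean, "-"),
                  2, model$scale$sd, "/")
    d <- mixed_dist_matrix(znum, if (is.null(catm)) NULL else
      catm[valid, , drop = FALSE],
      model$centers, model$centers_cat, model$lambda)
    lab[valid] <- max.col(-d, ties.method = "first")
  }
  labels <- grid_raster(matrix(lab, nrow(ref$values), ncol(ref$values)),
                        cell_size = ref$cell_size, xll = ref$xll,
                        yll = ref$yll, crs = ref$crs)
  new_efc_map(labels, model$k)
}

new_efc_map <- function(labels, k, constellations = NULL) {
  structure(list(labels = labels, k = k, areas = efc_areas(labels, k),
                 constellations = constellations),
            class = "efc_map")
}

efc_areas <- function(labels, k) {
  cell_ha <- labels$cell_size^2 / 1e4
  cnt <- tabulate(as.vector(labels$values), nbins = k)
  tibble::tibble(efc = seq_len(k), cells = cnt, area_ha = cnt * cell_ha)
}

#' @export
print.efc_map <- function(x, ...) {
  cat(sprintf("<efc_map> %d EFCs over %d x %d cells\n", x$k,
              nrow(x$labels$values), ncol(x$labels$values)))
  print(x$areas)
  if (!is.null(x$constellations)) {
    cat(sprintf("  %d constellation(s)\n",
                length(unique(stats::na.omit(as.vector(x$constellations$values))))))
  }
  invisible(x)
}

#' Mask an EFC map to forest land cover
#'
#' Cells whose land cover is not in the declared forest code set become
#' missing; per-label areas are recomputed. Masking only removes area.
#'
#' @param efc_map An `efc_map`.
#' @param landcover Co-registered categorical `grid_raster`.
#' @param forest_classes Character vector of land-cover classes counted as
#'   forest (default `"forest"`).
#' @return The masked `efc_map`.
#' @export
apply_forest_mask <- function(efc_map, landcover, forest_classes = "forest") {
  stopifnot(inherits(efc_map, "efc_map"))
  if (length(forest_classes) == 0) stop("no forest classes declared")
  if (!gr_same_grid(efc_map$labels, landcover)) {
    stop("land cover raster is not co-registered with the EFC map")
  }
  lc <- if (!is.null(landcover$categories)) {
    landcover$categories[as.vector(landcover$values)]
  } else as.character(as.vector(landcover$values))
  keep <- !is.na(lc) & lc %in% forest_classes
  v <- efc_map$labels$values
  v[!matrix(keep, nrow(v), ncol(v))] <- NA
  labels <- efc_map$labels
  labels$values <- v
  new_efc_map(labels, efc_map$k)
}

#' Group contiguous labelled area into constellations
#'
#' Connected components (8-connectivity) of the labelled cells are candidate
#' constellations; components whose area is at or below `min_area_ha` are
#' left unassigned. A constellation is expected to contain from 1 to 6
#' distinct EFC labels; a warning is recorded otherwise.
#'
#' @param efc_map An `efc_map`.
#' @param min_area_ha Minimum constellation area in hectares (default
#'   50000).
#' @param max_efcs Maximum expected number of distinct EFCs per
#'   constellation (default 6).
#' @return The `efc_map` with a `constellations` id raster and a
#'   `constellation_summary` tibble (`constellation`, `area_ha`, `n_efcs`).
#' @export
group_constellations <- function(efc_map, min_area_ha = 50000, max_efcs = 6) {
  stopifnot(inherits(efc_map, "efc_map"))
  lab <- efc_map$labels$values
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(!is.na(lab))
  cons <- matrix(NA_real_, nr, nc)
  summary <- tibble::tibble(constellation = integer(), area_ha = numeric(),
                            n_efcs = integer())
  if (length(idx)) {
    pos <- match(idx, idx)
    ri <- (idx - 1) %% nr + 1
    ci <- (idx - 1) %/% nr + 1
    # 8-neighbour edges among labelled cells
    offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
    edges <- NULL
    cellno <- matrix(NA_integer_, nr, nc)
    cellno[idx] <- seq_along(idx)
    for (o in seq_len(nrow(offs))) {
      r2 <- ri + offs[o, 1]; c2 <- ci + offs[o, 2]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      j <- cellno[cbind(r2[ok], c2[ok])]
      keep <- !is.na(j)
      edges <- rbind(edges, cbind(pos[ok][keep], j[keep]))
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (!is.null(edges) && nrow(edges) > 0) {
      g <- igraph::add_edges(g, t(edges))
    }
    comp <- igraph::components(g)$membership
    cell_ha <- efc_map$labels$cell_size^2 / 1e4
    comp_area <- tapply(rep(cell_ha, length(comp)), comp, sum)
    big <- as.integer(names(comp_area)[comp_area > min_area_ha])
    id_map <- setNames(seq_along(big), big)
    assigned <- comp %in% big
    cons[idx[assigned]] <- id_map[as.character(comp[assigned])]
    if (length(big)) {
      summary <- purrr::map_dfr(seq_along(big), function(i) {
        cells <- idx[comp == big[i]]
        n_efcs <- length(unique(lab[cells]))
        tibble::tibble(constellation = i,
                       area_ha = unname(comp_area[as.character(big[i])]),
                       n_efcs = n_efcs)
      })
      bad <- summary$n_efcs > max_efcs
      if (any(bad)) {
        warning(sprintf("constellation(s) %s contain more than %d EFCs",
                        paste(summary$constellation[bad], collapse = ", "),
                        max_efcs))
      }
    }
  }
  out <- efc_map
  out$constellations <- grid_raster(cons,
                                    cell_size = efc_map$labels$cell_size,
                                    xll = efc_map$labels$xll,
                                    yll = efc_map$labels$yll,
                                    crs = efc_map$labels$crs)
  out$constellation_summary <- summary
  out
}

#' Read a vegetation class-mapping file
#'
#' Maps source vegetation classes to functional groups (formation,
#' macroclimate, continentality are collapsed upstream); the file is a CSV
#' with columns `source_class`, `functional_group`.
#'
#' @param path CSV path.
#' @return Named character vector (`source_class` -> `functional_group`).
#' @export
read_class_mapping <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("source_class", "functional_group") %in% names(df)))
  setNames(df$functional_group, df$source_class)
}

#' Plot an EFC map
#'
#' @param object An `efc_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.efc_map <- function(object, ...) {
  df <- as_tibble.grid_raster(object$labels, drop_na = TRUE)
  df$efc <- factor(df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$efc)) +
    ggplot2::geom_raster() + ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)", fill = "EFC")
}
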