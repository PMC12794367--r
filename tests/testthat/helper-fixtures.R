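# shared helpers: tiny EFC maps and flux series built in code

make_efc_map <- function(label_matrix, k = max(label_matrix, na.rm = TRUE),
                         cell_size = 30) {
  labels <- grid_raster(label_matrix, cell_size = cell_size)
  structure(list(labels = labels, k = k,
                 areas = forestcarbon:::efc_areas(labels, k),
                 constellations = NULL),
            class = "efc_map")
}

# constant-flux series on the half-hour lattice
make_flat_series <- function(n, nee = 1, start = "2024-01-01") {
  tibble::tibble(
    timestamp = as.POSIXct(paste(start, "00:00:00"), tz = "UTC") +
      (seq_len(n) - 1) * 1800,
    nee = nee, quality_state = "measured", screen_reason = NA_character_
  )
}

# mixed two-group data with planted separation (in pooled SDs)
make_two_groups <- function(n_per = 6, sep = 10, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    grp = rep(c("a", "b"), each = n_per),
    x = c(rnorm(n_per, 0, 1), rnorm(n_per, sep, 1)),
    y = c(rnorm(n_per, 0, 1), rnorm(n_per, sep, 1)),
    veg = rep(c("forest", "shrub"), each = n_per)
  )
}

# exhaustive-assignment oracle: best k=2 partition under the mixed
# dissimilarity (standardized numerics + lambda * categorical mismatch)
brute_force_k2 <- function(data, numeric_cols, cat_cols, lambda) {
  num <- as.matrix(data[numeric_cols])
  z <- scale(num)
  catm <- as.matrix(data[cat_cols])
  n <- nrow(z)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    assign <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(assign)) < 2) next
    obj <- 0
    for (j in 1:2) {
      idx <- assign == j
      ctr <- colMeans(z[idx, , drop = FALSE])
      obj <- obj + sum(sweep(z[idx, , drop = FALSE], 2, ctr, "-")^2)
      for (cc in seq_len(ncol(catm))) {
        mode <- names(which.max(table(catm[idx, cc])))
        obj <- obj + lambda * sum(catm[idx, cc] != mode)
      }
    }
    if (is.null(best) || obj < best$obj) best <- list(obj = obj, assign = assign)
  }
  best
}

same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
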