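# Minimal in-memory raster container. Values live in a numeric matrix whose
# first row is the northern edge; categorical layers store integer codes plus
# a `categories` lookup. Georeference is lower-left corner + square cell.

#' Create a grid raster
#'
#' Lightweight matrix-backed raster used throughout the package. Row 1 of the
#' matrix is the northernmost row. Missing cells are `NA`.
#'
#' @param values Numeric (or integer) matrix of cell values.
#' @param cell_size Cell edge length in metres (default 30).
#' @param xll,yll Coordinates of the lower-left corner (default 0).
#' @param crs Coordinate reference system label, default `"EPSG:32718"`.
#' @param categories Optional character vector mapping integer codes
#'   `1..length(categories)` to category labels (categorical layers).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size = 30, xll = 0, yll = 0,
                        crs = "EPSG:32718", categories = NULL) {
  stopifnot(is.matrix(values), nrow(values) >= 1, ncol(values) >= 1,
            cell_size > 0)
  structure(
    list(values = values, cell_size = cell_size, xll = xll, yll = yll,
         crs = crs, categories = categories),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d cells, %g m, %s\n",
              nrow(v), ncol(v), x$cell_size, x$crs))
  if (!is.null(x$categories)) {
    cat("  categorical:", paste(x$categories, collapse = ", "), "\n")
  } else {
    cat(sprintf("  values: [%.4g, %.4g], %d NA\n",
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  }
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

# cell-center coordinates; row 1 = north
gr_coords <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(
    x = r$xll + (seq_len(nc) - 0.5) * r$cell_size,
    y = r$yll + (nr - seq_len(nr) + 0.5) * r$cell_size
  )
}

gr_same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$xll, b$xll)) && isTRUE(all.equal(a$yll, b$yll))
}

#' Convert a grid raster to a tibble
#'
#' @param x A `grid_raster`.
#' @param ... Unused.
#' @param drop_na Drop `NA` cells (default `FALSE`).
#' @return Tibble with `row`, `col`, `x`, `y`, `value` (and `label` for
#'   categorical layers).
#' @export
as_tibble.grid_raster <- function(x, ..., drop_na = FALSE) {
  cc <- gr_coords(x)
  out <- tibble::tibble(
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  out$x <- cc$x[out$col]
  out$y <- cc$y[out$row]
  if (!is.null(x$categories)) {
    out$label <- x$categories[out$value]
  }
  if (drop_na) out <- out[!is.na(out$value), ]
  out[, c("row", "col", "x", "y", setdiff(names(out), c("row", "col", "x", "y")))]
}

#' Write a grid raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster format (`.asc`); the `-9999` sentinel
#' encodes missing cells.
#'
#' @param r A `grid_raster`.
#' @param path Output file path.
#' @param nodata Sentinel value, default -9999.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", r$xll),
    sprintf("yllcorner %.6f", r$yll),
    sprintf("cellsize %.6f", r$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1, function(row) paste(format(row, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param crs CRS label to attach, default `"EPSG:32718"`.
#' @param categories Optional category labels for categorical layers.
#' @return A `grid_raster`.
#' @export
read_ascii_grid <- function(path, crs = "EPSG:32718", categories = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid_raster(m, cell_size = hdr$cellsize, xll = hdr$xllcorner,
              yll = hdr$yllcorner, crs = crs, categories = categories)
}

#' Block-aggregate a raster to a coarser resolution
#'
#' @param r A `grid_raster`.
#' @param factor Integer aggregation factor (coarse cell = `factor` x
#'   `factor` fine cells).
#' @param fun `"mean"` (valid-cell block mean) or `"majority"` (modal value,
#'   for categorical layers).
#' @return Coarser `grid_raster`. Blocks that are entirely missing are `NA`.
#' @export
aggregate_raster <- function(r, factor, fun = c("mean", "majority")) {
  fun <- match.arg(fun)
  stopifnot(factor >= 1, factor == round(factor))
  v <- r$values
  if (nrow(v) %% factor != 0 || ncol(v) %% factor != 0) {
    stop("raster dimensions must be a multiple of the aggregation factor")
  }
  nr <- nrow(v) %/% factor; nc <- ncol(v) %/% factor
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      block <- v[((i - 1) * factor + 1):(i * factor),
                 ((j - 1) * factor + 1):(j * factor)]
      b <- block[!is.na(block)]
      if (length(b) == 0) next
      out[i, j] <- if (fun == "mean") mean(b) else
        as.numeric(names(which.max(table(b))))
    }
  }
  grid_raster(out, cell_size = r$cell_size * factor, xll = r$xll, yll = r$yll,
              crs = r$crs, categories = r$categories)
}

#' Plot a grid raster
#'
#' @param object A `grid_raster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_raster <- function(object, ...) {
  df <- as_tibble.grid_raster(object, drop_na = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(object$categories)) {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$label))
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c()
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)")
}
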