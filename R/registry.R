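# Property-level carbon accounting: per-EFC areas inside property
# boundaries, accrual of whole-ton net-removal units with carried residual,
# and an append-only hash-chained ledger. One unit is one metric ton (Mg)
# of CO2 net removed by the ecosystem.

#' Register a property against an EFC map
#'
#' Computes the area of each eco-functional cluster inside the property
#' boundary by cell counting (a cell belongs to the property when its centre
#' is inside the polygon). The productive area is the total labelled
#' (forested) area.
#'
#' @param boundary Two-column matrix of polygon vertices (same CRS/units as
#'   the map) or a GeoJSON file path with a single Polygon.
#' @param efc_map An `efc_map` (after forest masking, so labelled cells are
#'   forest).
#' @param entry_date Entry date of the property (default today).
#' @param property_id Identifier string.
#' @param station_id Linked monitoring-station id (optional).
#' @return A `property_record`: `property_id`, `entry_date`, `areas`
#'   (tibble of `efc`, `area_ha`), `productive_area_ha`, `station_id`,
#'   `boundary`.
#' @export
register_property <- function(boundary, efc_map, entry_date = Sys.Date(),
                              property_id = "property-1",
                              station_id = NA_character_) {
  stopifnot(inherits(efc_map, "efc_map"))
  if (is.character(boundary)) boundary <- read_geojson_polygon(boundary)
  if (!is.matrix(boundary) || nrow(boundary) < 3) stop("invalid boundary")
  lab <- efc_map$labels
  cc <- gr_coords(lab)
  pts_x <- rep(cc$x, each = nrow(lab$values))
  pts_y <- rep(cc$y, ncol(lab$values))
  inside <- pracma::inpolygon(pts_x, pts_y, boundary[, 1], boundary[, 2])
  labv <- as.vector(lab$values)
  sel <- inside & !is.na(labv)
  if (!any(inside)) stop("boundary does not overlap the EFC map")
  if (!any(sel)) stop("boundary contains no labelled EFC cells")
  cell_ha <- lab$cell_size^2 / 1e4
  cnt <- tabulate(labv[sel], nbins = efc_map$k)
  areas <- tibble::tibble(efc = seq_len(efc_map$k), area_ha = cnt * cell_ha)
  structure(list(property_id = property_id,
                 entry_date = as.Date(entry_date),
                 areas = areas[areas$area_ha > 0, ],
                 productive_area_ha = sum(cnt) * cell_ha,
                 station_id = station_id, boundary = boundary),
            class = "property_record")
}

#' @export
print.property_record <- function(x, ...) {
  cat(sprintf("<property_record> %s (entered %s): %.1f ha productive\n",
              x$property_id, format(x$entry_date), x$productive_area_ha))
  print(x$areas)
  invisible(x)
}

read_geojson_polygon <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- if (!is.null(gj$features)) gj$features[[1]]$geometry else
    if (!is.null(gj$geometry)) gj$geometry else gj
  if (is.null(geom$type) || geom$type != "Polygon") {
    stop("expected a GeoJSON Polygon")
  }
  ring <- geom$coordinates[[1]]
  do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
}

#' Create an empty carbon-unit ledger
#'
#' @param hash_algorithm Digest algorithm recorded per entry (only
#'   `"sha256"` is implemented).
#' @return A `carbon_ledger` (zero-row tibble with the ledger schema).
#' @export
carbon_ledger <- function(hash_algorithm = "sha256") {
  stopifnot(hash_algorithm == "sha256")
  structure(tibble::tibble(
    index = integer(), timestamp = character(), property_id = character(),
    gross_absorbed = numeric(), gross_emitted = numeric(),
    net_contribution = numeric(), cumulative_balance = numeric(),
    units_issued = integer(), residual = numeric(),
    hash_algorithm = character(), prev_hash = character(),
    entry_hash = character()),
    class = c("carbon_ledger", "tbl_df", "tbl", "data.frame"))
}

ledger_head_hash <- function(ledger) {
  if (nrow(ledger) == 0) GENESIS_HASH else ledger$entry_hash[nrow(ledger)]
}

GENESIS_HASH <- strrep("0", 64)

entry_digest <- function(entry) {
  fields <- entry[sort(setdiff(names(entry), "entry_hash"))]
  sha256(jsonlite::toJSON(fields, auto_unbox = TRUE, digits = 10))
}

#' Accrue a monitoring period into a ledger entry
#'
#' Net removal for the period is
#' `sum over EFCs of (-NEE_footprint * P_Ext(EFC) * area_EFC)` (Mg CO2).
#' When positive, whole units are issued as the floor of the removal plus
#' the carried residual, and the fractional remainder is carried forward;
#' when non-positive, no units are issued and the cumulative balance
#' decreases. A stale extrapolation factor (outside its validity window) is
#' refused.
#'
#' @param property A [register_property()] record.
#' @param nee_period Footprint-measured NEE for the period (Mg CO2 ha-1
#'   period-1; negative = uptake).
#' @param pext Named list/vector of [compute_pext()] factors (or bare
#'   numbers) keyed by EFC id as character; bare numbers are treated as
#'   always valid.
#' @param ledger The current `carbon_ledger` (supplies the carried residual
#'   and running balance for this property).
#' @param timestamp Period timestamp (ISO-8601 string or date-time).
#' @return The ledger with the new entry appended (hash-chained).
#' @export
accrue <- function(property, nee_period, pext, ledger,
                   timestamp = Sys.time()) {
  stopifnot(inherits(property, "property_record"),
            inherits(ledger, "carbon_ledger"))
  period_date <- as.Date(timestamp)
  contrib <- vapply(seq_len(nrow(property$areas)), function(i) {
    efc <- as.character(property$areas$efc[i])
    p <- if (!is.null(names(pext)) && efc %in% names(pext)) pext[[efc]] else
      stop("no extrapolation factor for EFC ", efc)
    if (inherits(p, "pext_factor")) {
      if (period_date > p$valid_until || period_date < p$date) {
        stop(sprintf("extrapolation factor for EFC %s is stale (valid %s to %s)",
                     efc, format(p$date), format(p$valid_until)))
      }
      p <- p$value
    }
    -nee_period * p * property$areas$area_ha[i]
  }, numeric(1))
  net <- sum(contrib)

  prior <- ledger[ledger$property_id == property$property_id, ]
  carried <- if (nrow(prior)) prior$residual[nrow(prior)] else 0
  balance <- if (nrow(prior)) prior$cumulative_balance[nrow(prior)] else 0

  if (net > 0) {
    total <- net + carried
    units <- as.integer(floor(total))
    residual <- total - units
    absorbed <- net; emitted <- 0
  } else {
    units <- 0L
    residual <- carried
    absorbed <- 0; emitted <- -net
  }
  entry <- list(
    index = nrow(ledger) + 1L,
    timestamp = format(as.POSIXct(timestamp, tz = "UTC"),
                       "%Y-%m-%dT%H:%M:%SZ"),
    property_id = property$property_id,
    gross_absorbed = absorbed, gross_emitted = emitted,
    net_contribution = net, cumulative_balance = balance + net,
    units_issued = units, residual = residual,
    hash_algorithm = "sha256", prev_hash = ledger_head_hash(ledger))
  append_entry(ledger, entry)
}

#' Append a prepared entry to the ledger
#'
#' The entry must reference the current head hash; its own hash is the
#' digest of the canonical (sorted-key JSON) serialization including the
#' previous hash.
#'
#' @param ledger A `carbon_ledger`.
#' @param entry Named list with the ledger schema fields (minus
#'   `entry_hash`).
#' @return The grown ledger.
#' @export
append_entry <- function(ledger, entry) {
  stopifnot(inherits(ledger, "carbon_ledger"))
  if (!identical(entry$prev_hash, ledger_head_hash(ledger))) {
    stop("entry does not reference the current head hash")
  }
  entry$entry_hash <- entry_digest(entry)
  out <- dplyr::bind_rows(ledger, tibble::as_tibble(entry))
  class(out) <- class(ledger)
  out
}

#' Verify the ledger hash chain
#'
#' Recomputes every digest and checks the chaining; deterministic and
#' order-sensitive, so any single-field mutation is detected.
#'
#' @param ledger A `carbon_ledger`.
#' @return Index (row) of the first invalid entry, or `NA_integer_` when
#'   the whole chain verifies (including an empty ledger).
#' @export
verify_chain <- function(ledger) {
  stopifnot(inherits(ledger, "carbon_ledger"))
  prev <- GENESIS_HASH
  for (i in seq_len(nrow(ledger))) {
    entry <- as.list(ledger[i, ])
    if (!identical(entry$prev_hash, prev)) return(i)
    if (!identical(entry_digest(entry), entry$entry_hash)) return(i)
    prev <- entry$entry_hash
  }
  NA_integer_
}

#' Snapshot report of a ledger
#'
#' @param ledger A `carbon_ledger`.
#' @param scope Optional property ids to restrict to.
#' @return List with `by_property` (tibble: units, residual, gross flows,
#'   balance per property) and `totals` (one-row tibble). Conservation
#'   holds: issued units plus current residual equal the cumulative
#'   positive net removals.
#' @export
ledger_snapshot <- function(ledger, scope = NULL) {
  stopifnot(inherits(ledger, "carbon_ledger"))
  df <- if (is.null(scope)) ledger else
    ledger[ledger$property_id %in% scope, ]
  if (nrow(df) == 0) {
    empty <- tibble::tibble(property_id = character(), units = integer(),
                            residual = numeric(), gross_absorbed = numeric(),
                            gross_emitted = numeric(), balance = numeric())
    return(list(by_property = empty,
                totals = tibble::tibble(units = 0L, residual = 0,
                                        gross_absorbed = 0, gross_emitted = 0,
                                        balance = 0)))
  }
  by_prop <- df |>
    dplyr::group_by(.data$property_id) |>
    dplyr::summarise(units = sum(.data$units_issued),
                     residual = .data$residual[dplyr::n()],
                     gross_absorbed = sum(.data$gross_absorbed),
                     gross_emitted = sum(.data$gross_emitted),
                     balance = .data$cumulative_balance[dplyr::n()],
                     .groups = "drop")
  totals <- tibble::tibble(units = sum(by_prop$units),
                           residual = sum(by_prop$residual),
                           gross_absorbed = sum(by_prop$gross_absorbed),
                           gross_emitted = sum(by_prop$gross_emitted),
                           balance = sum(by_prop$balance))
  list(by_property = by_prop, totals = totals)
}

#' Write / read a ledger as JSON lines
#'
#' @param ledger A `carbon_ledger`.
#' @param path File path (`.jsonl`).
#' @return `path` / the ledger.
#' @export
write_ledger <- function(ledger, path) {
  lines <- vapply(seq_len(nrow(ledger)), function(i)
    as.character(jsonlite::toJSON(as.list(ledger[i, ]), auto_unbox = TRUE,
                                  digits = 10)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  lines <- readLines(path)
  out <- carbon_ledger()
  for (l in lines) {
    e <- jsonlite::fromJSON(l)
    e$index <- as.integer(e$index)
    e$units_issued <- as.integer(e$units_issued)
    out <- dplyr::bind_rows(out, tibble::as_tibble(e))
  }
  class(out) <- class(carbon_ledger())
  out
}
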