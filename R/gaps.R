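#' Classify a gap by length and extent
#'
#' Monitoring-series gaps fall into three classes: short isolated gaps of up
#' to 5 h at a single station, longer isolated gaps of 6 h or more, and gaps
#' occurring at all stations of the network simultaneously.
#'
#' @param length Gap length in hours (>= 1).
#' @param network_wide Logical: does the gap span every station?
#' @return One of `"short_single"`, `"long_single"`, `"multi_station"`.
#' @examples
#' classify_gap(5, FALSE)  # short_single
#' classify_gap(6, FALSE)  # long_single
#' @export
classify_gap <- function(length, network_wide = FALSE) {
  stop_if_not(all(length >= 1), "gap length must be >= 1 hour")
  ifelse(rep_len(network_wide, length(length)), "multi_station",
         ifelse(length <= 5, "short_single", "long_single"))
}

new_gap_inventory <- function(records, n_stations) {
  if (nrow(records) == 0) {
    records <- data.frame(station_id = character(), start = as.POSIXct(character(), tz = "UTC"),
                          start_index = integer(), length = integer(),
                          gap_class = character(), bounded_left = logical(),
                          bounded_right = logical(), stringsAsFactors = FALSE)
  }
  structure(records, class = c("gap_inventory", "data.frame"),
            n_stations = n_stations)
}

#' Detect and classify maximal gaps in a panel
#'
#' Finds every maximal run of missing cells. Hours at which *all* stations
#' are missing form network-wide `multi_station` records (station id `"ALL"`,
#' each missing cell counted once); the remaining per-station runs are split
#' at multi-station block boundaries and classified by [classify_gap()].
#' Runs with no observed value on one side (panel edge or adjacent
#' multi-station block) are flagged unbounded, which the linear interpolator
#' uses to skip them.
#'
#' @param panel A [series_panel()].
#' @return A `gap_inventory`: data frame of records with columns
#'   `station_id`, `start`, `start_index`, `length`, `gap_class`,
#'   `bounded_left`, `bounded_right`.
#' @export
detect_gaps <- function(panel) {
  v <- panel$values
  n_s <- nrow(v); n_t <- ncol(v)
  # a network-wide outage needs a network: with a single station every run
  # is a single-station gap
  allmiss <- if (n_s > 1) colSums(is.na(v)) == n_s else rep(FALSE, n_t)
  recs <- list()
  runs_of <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], len = r$lengths[r$values])
  }
  mruns <- runs_of(allmiss)
  if (nrow(mruns) > 0) {
    recs[[length(recs) + 1L]] <- data.frame(
      station_id = "ALL",
      start = panel$timestamps[mruns[, "start"]],
      start_index = as.integer(mruns[, "start"]),
      length = as.integer(mruns[, "len"]),
      gap_class = "multi_station",
      bounded_left = mruns[, "start"] > 1L,
      bounded_right = mruns[, "start"] + mruns[, "len"] - 1L < n_t,
      stringsAsFactors = FALSE)
  }
  for (s in seq_len(n_s)) {
    miss <- is.na(v[s, ]) & !allmiss  # multi-station hours excluded
    if (!any(miss)) next
    sruns <- runs_of(miss)
    # a run endpoint adjacent to a multi-station block is unbounded there
    st <- sruns[, "start"]; en <- st + sruns[, "len"] - 1L
    bl <- st > 1L & !allmiss[pmax(st - 1L, 1L)]
    br <- en < n_t & !allmiss[pmin(en + 1L, n_t)]
    recs[[length(recs) + 1L]] <- data.frame(
      station_id = panel$stations[s],
      start = panel$timestamps[st],
      start_index = as.integer(st),
      length = as.integer(sruns[, "len"]),
      gap_class = classify_gap(sruns[, "len"], FALSE),
      bounded_left = bl, bounded_right = br,
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(station_id = character(), start = as.POSIXct(character(), tz = "UTC"),
               start_index = integer(), length = integer(), gap_class = character(),
               bounded_left = logical(), bounded_right = logical())
  out <- out[order(out$station_id != "ALL", out$station_id, out$start_index), ]
  rownames(out) <- NULL
  inv <- new_gap_inventory(out, n_s)
  # sum rule: every missing cell covered exactly once
  covered <- gap_cell_count(inv)
  stop_if_not(covered == sum(is.na(v)),
              "internal error: gap records do not cover missing cells exactly")
  inv
}

# Total missing cells implied by an inventory (multi-station records cover
# all stations).
gap_cell_count <- function(inventory) {
  if (nrow(inventory) == 0) return(0L)
  n_s <- attr(inventory, "n_stations")
  multi <- inventory$gap_class == "multi_station"
  sum(inventory$length[!multi]) + sum(inventory$length[multi]) * n_s
}

#' @export
print.gap_inventory <- function(x, ...) {
  cat(sprintf("gap_inventory: %d records (%d short_single, %d long_single, %d multi_station)\n",
              nrow(x), sum(x$gap_class == "short_single"),
              sum(x$gap_class == "long_single"),
              sum(x$gap_class == "multi_station")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Missing-data summary by gap class
#'
#' @param inventory A `gap_inventory` from [detect_gaps()].
#' @param panel The [series_panel()] the inventory was derived from.
#' @return List with `overall` (missing cells / total cells) and
#'   `class_shares`, the fraction of missing cells attributable to each gap
#'   class (sums to 1 when any cell is missing).
#' @export
missingness_summary <- function(inventory, panel) {
  total <- length(panel$values)
  miss <- n_missing(panel)
  stop_if_not(gap_cell_count(inventory) == miss,
              "inventory does not match panel missingness")
  n_s <- attr(inventory, "n_stations")
  cells <- function(cls) {
    sel <- inventory$gap_class == cls
    if (cls == "multi_station") sum(inventory$length[sel]) * n_s
    else sum(inventory$length[sel])
  }
  shares <- c(short_single = cells("short_single"),
              long_single = cells("long_single"),
              multi_station = cells("multi_station"))
  list(overall = miss / total,
       class_shares = if (miss > 0) shares / miss else shares * 0)
}
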