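#' Hourly concentration panels
#'
#' A `series_panel` holds an hourly station-by-time matrix of pollutant
#' concentrations (ppb) with explicit missingness (`NA`). The time axis is a
#' strictly increasing, gap-free hourly grid of timezone-naive wall-clock
#' hours (stored as UTC `POSIXct`); missing observations are `NA` cells, never
#' absent columns.
#'
#' @param values Numeric matrix, stations in rows, hours in columns. Cells are
#'   finite non-negative concentrations or `NA`.
#' @param stations Character vector of unique station ids, one per row.
#' @param timestamps `POSIXct` vector of hourly timestamps, one per column.
#' @return An object of class `series_panel`.
#' @examples
#' ts <- seq(as.POSIXct("2011-01-01", tz = "UTC"), by = "hour", length.out = 4)
#' p <- series_panel(matrix(c(30, NA, 32, 33, 40, 41, NA, 43), 2, 4, byrow = TRUE),
#'                   c("s1", "s2"), ts)
#' n_missing(p)
#' @export
series_panel <- function(values, stations, timestamps) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stations <- as.character(stations)
  stop_if_not(nrow(values) == length(stations),
              "values must have one row per station")
  stop_if_not(ncol(values) == length(timestamps),
              "values must have one column per timestamp")
  stop_if_not(!anyDuplicated(stations), "station ids must be unique")
  timestamps <- as.POSIXct(as.numeric(as.POSIXct(timestamps, tz = "UTC")),
                           origin = "1970-01-01", tz = "UTC")
  if (length(timestamps) > 1) {
    d <- diff(as.numeric(timestamps))
    stop_if_not(all(d == 3600), "timestamps must form a strict hourly grid")
  }
  ok <- is.na(values) | (is.finite(values) & values >= 0)
  stop_if_not(all(ok), "values must be finite and non-negative or NA")
  dimnames(values) <- NULL
  structure(list(values = values, stations = stations, timestamps = timestamps),
            class = "series_panel")
}

#' @export
print.series_panel <- function(x, ...) {
  cat(sprintf("series_panel: %d stations x %d hours (%s .. %s), %.1f%% missing\n",
              length(x$stations), length(x$timestamps),
              format(x$timestamps[1]), format(x$timestamps[length(x$timestamps)]),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
summary.series_panel <- function(object, ...) {
  v <- object$values
  cat(sprintf("series_panel with %d stations, %d hours\n",
              nrow(v), ncol(v)))
  cat(sprintf("  missing cells: %d / %d (%.2f%%)\n",
              sum(is.na(v)), length(v), 100 * mean(is.na(v))))
  print(summary(as.vector(v)))
  invisible(object)
}

#' Number of missing cells in a panel
#' @param panel A [series_panel()].
#' @return Integer count of missing cells.
#' @export
n_missing <- function(panel) sum(is.na(panel$values))

#' Read an hourly panel from a long-format CSV file
#'
#' The file must have columns `station_id`, `timestamp`, `value` (empty value
#' = missing). The panel is densified to the full hourly grid spanning the
#' minimum to maximum timestamp in the file; absent (station, hour) rows
#' become missing cells.
#'
#' @param path Path to a CSV file.
#' @return A [series_panel()].
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(station_id = "character",
                                       timestamp = "character",
                                       value = "numeric"))
  stop_if_not(all(c("station_id", "timestamp", "value") %in% names(df)),
              "panel file needs columns station_id, timestamp, value")
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M",
                                  "%Y-%m-%d %H:%M"))
  stop_if_not(!anyNA(ts), "unparseable timestamps in panel file")
  stop_if_not(all(as.numeric(ts) %% 3600 == 0),
              "non-hourly timestamps in panel file")
  dup <- duplicated(paste(df$station_id, as.numeric(ts)))
  if (any(dup)) {
    stop(sprintf("duplicate (station, timestamp) pairs at rows: %s",
                 paste(which(dup), collapse = ", ")), call. = FALSE)
  }
  stations <- sort(unique(df$station_id))
  grid <- seq(min(ts), max(ts), by = "hour")
  vals <- matrix(NA_real_, length(stations), length(grid))
  si <- match(df$station_id, stations)
  ti <- as.integer((as.numeric(ts) - as.numeric(grid[1])) / 3600) + 1L
  vals[cbind(si, ti)] <- df$value
  series_panel(vals, stations, grid)
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_panel()]: writes one row per (station, hour), with an
#' empty `value` field for missing cells, so a read/write round-trip is
#' lossless.
#'
#' @param panel A [series_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  n_s <- length(panel$stations); n_t <- length(panel$timestamps)
  df <- data.frame(
    station_id = rep(panel$stations, times = n_t),
    timestamp = rep(format(panel$timestamps, "%Y-%m-%dT%H:%M:%SZ"), each = n_s),
    value = as.vector(panel$values),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a station metadata table
#'
#' Validates the fields used for graph construction and as static auxiliary
#' features: coordinates, altitude above sea level, relative altitude (height
#' above the lowest point within 5 km), population density, nightlight
#' intensity, and the categorical station and area types.
#'
#' @param station_id Character ids (unique).
#' @param latitude,longitude Degrees.
#' @param altitude,relative_altitude Meters.
#' @param population_density Persons per square km.
#' @param nightlight Arbitrary intensity units.
#' @param station_type,area_type Categorical (character or factor).
#' @return A `data.frame` with class `station_table`.
#' @export
station_table <- function(station_id, latitude, longitude, altitude,
                          relative_altitude, population_density, nightlight,
                          station_type, area_type) {
  station_id <- as.character(station_id)
  stop_if_not(!anyDuplicated(station_id), "station ids must be unique")
  stop_if_not(all(latitude >= -90 & latitude <= 90), "latitude out of range")
  stop_if_not(all(longitude >= -180 & longitude <= 180), "longitude out of range")
  df <- data.frame(station_id = station_id, latitude = latitude,
                   longitude = longitude, altitude = altitude,
                   relative_altitude = relative_altitude,
                   population_density = population_density,
                   nightlight = nightlight,
                   station_type = as.character(station_type),
                   area_type = as.character(area_type),
                   stringsAsFactors = FALSE)
  class(df) <- c("station_table", "data.frame")
  df
}

#' Read / write a station table as CSV
#' @param path CSV path with the [station_table()] columns.
#' @return A `station_table`.
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(station_id = "character"))
  do.call(station_table, df[c("station_id", "latitude", "longitude", "altitude",
                              "relative_altitude", "population_density",
                              "nightlight", "station_type", "area_type")])
}

#' @rdname read_stations
#' @param stations A [station_table()].
#' @export
write_stations <- function(stations, path) {
  utils::write.csv(as.data.frame(stations), path, row.names = FALSE)
  invisible(path)
}

# The fixed 19-feature auxiliary vector, in canonical column order.
FEATURE_NAMES <- c(
  "hour_of_day", "day_of_week", "day_of_year",
  "temperature", "relative_humidity", "cloud_cover", "pbl_height",
  "wind_u", "wind_v",
  "reanalysis_o3", "reanalysis_no", "reanalysis_no2",
  "emissions_nox",
  "altitude", "relative_altitude", "population_density", "nightlight",
  "station_type", "area_type"
)

#' Names of the 19 auxiliary features
#'
#' The canonical order of the per-(station, hour) auxiliary feature vector:
#' three datetime features, six meteorological drivers, three reanalysis
#' concentrations, one emission field, and six static station metadata
#' features (the two categorical ones integer-encoded).
#'
#' @return Character vector of length 19.
#' @export
feature_names <- function() FEATURE_NAMES

#' Construct a feature table
#'
#' A feature table has one row per (station, hour) with the 19 auxiliary
#' features of [feature_names()] in fixed order, keyed by `station_id` and
#' `timestamp`. Rows are ordered station-major (all hours of the first
#' station, then the second, ...), matching the node order of the
#' spatiotemporal graph.
#'
#' @param station_id,timestamp Row keys.
#' @param features Numeric matrix or data.frame with the 19 columns of
#'   [feature_names()].
#' @return A `data.frame` with class `feature_table`.
#' @export
feature_table <- function(station_id, timestamp, features) {
  features <- as.data.frame(features)
  stop_if_not(identical(names(features), FEATURE_NAMES),
              "features must have exactly the 19 canonical columns in order")
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  lt <- as.POSIXlt(timestamp)
  stop_if_not(all(features$hour_of_day == lt$hour),
              "hour_of_day inconsistent with timestamp")
  stop_if_not(all(features$day_of_year == lt$yday + 1L),
              "day_of_year inconsistent with timestamp")
  df <- cbind(data.frame(station_id = as.character(station_id),
                         timestamp = timestamp, stringsAsFactors = FALSE),
              features)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @rdname feature_table
#' @param path CSV path.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(station_id = "character",
                                       timestamp = "character"))
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S"))
  feature_table(df$station_id, ts, df[FEATURE_NAMES])
}

#' @rdname feature_table
#' @param x A `feature_table`.
#' @export
write_features <- function(x, path) {
  out <- as.data.frame(x)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Feature-table row index for station s (index) and hour t (index), given
# panel dimensions; station-major order.
ft_row <- function(s, t, n_hours) (s - 1L) * n_hours + t
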