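# Shared fixtures, built in code. Heavier simulations are memoized so several
# test files can reuse one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

hourly <- function(n, start = "2011-01-01 00:00:00") {
  seq(as.POSIXct(start, tz = "UTC"), by = "hour", length.out = n)
}

# Small panel from a values matrix (stations x hours).
mk_panel <- function(values, start = "2011-01-01 00:00:00") {
  series_panel(values, sprintf("s%d", seq_len(nrow(values))),
               hourly(ncol(values), start))
}

# Station table with explicit planar offsets (km east/north of a reference).
mk_stations <- function(x_km, y_km = rep(0, length(x_km))) {
  kmdeg <- 6371 * pi / 180
  station_table(sprintf("s%d", seq_along(x_km)),
                latitude = 51 + y_km / kmdeg,
                longitude = 10 + x_km / (kmdeg * cos(51 * pi / 180)),
                altitude = rep(100, length(x_km)),
                relative_altitude = rep(10, length(x_km)),
                population_density = rep(500, length(x_km)),
                nightlight = rep(20, length(x_km)),
                station_type = rep("background", length(x_km)),
                area_type = rep("rural", length(x_km)))
}

# Feature table where every feature is constant except `temperature`, which
# carries the given per-row values; datetime features stay consistent with
# the timestamps. Rows are station-major for a panel of the given shape.
mk_features_1d <- function(stations, timestamps, temperature) {
  n_s <- length(stations); n_t <- length(timestamps)
  lt <- as.POSIXlt(timestamps)
  f <- data.frame(
    hour_of_day = rep(lt$hour, times = n_s),
    day_of_week = rep(lt$wday, times = n_s),
    day_of_year = rep(lt$yday + 1L, times = n_s),
    temperature = temperature,
    relative_humidity = 0, cloud_cover = 0, pbl_height = 0,
    wind_u = 0, wind_v = 0, reanalysis_o3 = 0, reanalysis_no = 0,
    reanalysis_no2 = 0, emissions_nox = 0, altitude = 0,
    relative_altitude = 0, population_density = 0, nightlight = 0,
    station_type = 0, area_type = 0)
  feature_table(rep(stations, each = n_t), rep(timestamps, times = n_s), f)
}

# A two-node graph with a single unit edge and no self-loops; degrees are
# both 1, so S = [[0, 1], [1, 0]].
two_node_graph <- function() {
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 1),
                            dims = c(2, 2))
  list(A = A, degrees = Matrix::rowSums(A))
}

# Random symmetric weighted graph with self-loops, for oracle comparisons.
random_graph <- function(n, p_edge = 0.1) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p_edge]
  A[on] <- stats::runif(length(on), 0.1, 1)
  A <- A + t(A)
  diag(A) <- stats::runif(n, 0.5, 1)
  list(dense = A,
       graph = list(A = Matrix::Matrix(A, sparse = TRUE),
                    degrees = rowSums(A)))
}

# The default-scale synthetic study data set (30 stations x 2160 h, 15%
# missing, 17/57/26 gap mix), shared across tests.
default_net <- function() memo("default_net", simulate_network(synthetic_config(seed = 101)))
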