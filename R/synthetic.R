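#' Configuration for the synthetic network simulator
#'
#' The simulator emulates the statistical structure of an hourly ozone
#' monitoring network: a base concentration with seasonal and diurnal cycles,
#' a zero-mean residual field with exponential spatial covariance and AR(1)
#' temporal persistence, white measurement noise, auxiliary features
#' correlated with the latent drivers (plus one deliberately uninformative
#' reanalysis feature), and the three observed gap patterns (short isolated,
#' long isolated, network-wide) in configurable proportions.
#'
#' Defaults mirror the gap statistics of a year of preliminary German network
#' data: 15% missing overall, split 17/57/26 between short single-station
#' gaps (1-5 h), long single-station gaps (>= 6 h), and simultaneous
#' network-wide gaps (several 3-4 h gaps plus a few 18-43 h outages).
#'
#' @param n_stations Number of stations.
#' @param extent Side of the square domain, km.
#' @param n_hours Number of hourly time steps.
#' @param base_level Mean concentration, ppb.
#' @param seasonal_amplitude,diurnal_amplitude Cycle amplitudes, ppb.
#' @param spatial_corr_length e-folding length of the residual field's
#'   exponential spatial correlation, km.
#' @param temporal_corr AR(1) coefficient of the residual field in `[0, 1)`.
#' @param field_sd Marginal standard deviation of the residual field, ppb.
#' @param noise_sd White measurement noise, ppb.
#' @param gap_mix Proportions of missing cells in the three classes
#'   (short_single, long_single, multi_station); must sum to 1.
#' @param missing_fraction Overall fraction of cells made missing, `[0, 1)`.
#' @param seed Integer seed; every simulator operation is deterministic
#'   given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_stations = 30, extent = 300, n_hours = 2160,
                             base_level = 30, seasonal_amplitude = 10,
                             diurnal_amplitude = 10, spatial_corr_length = 100,
                             temporal_corr = 0.95, field_sd = 8, noise_sd = 2,
                             gap_mix = c(0.17, 0.57, 0.26),
                             missing_fraction = 0.15, seed = 1L) {
  stop_if_not(n_stations >= 1, "n_stations must be >= 1")
  stop_if_not(abs(sum(gap_mix) - 1) < 1e-8 && all(gap_mix >= 0),
              "gap_mix must be 3 non-negative proportions summing to 1")
  stop_if_not(length(gap_mix) == 3, "gap_mix must have 3 entries")
  stop_if_not(temporal_corr >= 0 && temporal_corr < 1,
              "temporal_corr must be in [0, 1)")
  stop_if_not(missing_fraction >= 0 && missing_fraction < 1,
              "missing_fraction must be in [0, 1)")
  stop_if_not(all(c(seasonal_amplitude, diurnal_amplitude, field_sd, noise_sd) >= 0),
              "amplitudes and standard deviations must be >= 0")
  structure(list(n_stations = as.integer(n_stations), extent = extent,
                 n_hours = as.integer(n_hours), base_level = base_level,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 spatial_corr_length = spatial_corr_length,
                 temporal_corr = temporal_corr, field_sd = field_sd,
                 noise_sd = noise_sd, gap_mix = gap_mix,
                 missing_fraction = missing_fraction, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Reference point for mapping the planar simulation domain to coordinates
# (central Germany). Conversion uses the same spherical radius as
# station_distance() (6371 km -> 111.195 km per degree of latitude), so
# great-circle distances between simulated stations track the planar ones.
REF_LAT <- 51.0
REF_LON <- 10.0
KM_PER_DEG <- 6371 * pi / 180

#' Simulate a station network
#'
#' Station locations are uniform in a square of side `extent` km, mapped to
#' latitude/longitude around a central-European reference point so that
#' great-circle distances approximate the planar distances. Metadata are
#' drawn from simple documented distributions: log-normal altitude and
#' population density, nightlight increasing with population density, and
#' categorical station/area types.
#'
#' @param config A [synthetic_config()].
#' @return A [station_table()] with an `xy_km` attribute holding the planar
#'   coordinates.
#' @export
simulate_stations <- function(config) {
  with_seed(sub_seed(config$seed, 1L), {
    n <- config$n_stations
    x <- stats::runif(n, 0, config$extent)
    y <- stats::runif(n, 0, config$extent)
    lat <- REF_LAT + (y - config$extent / 2) / KM_PER_DEG
    lon <- REF_LON + (x - config$extent / 2) /
      (KM_PER_DEG * cos(REF_LAT * pi / 180))
    altitude <- round(exp(stats::rnorm(n, log(200), 0.7)))
    relative_altitude <- round(altitude * stats::runif(n, 0.02, 0.4))
    population_density <- round(exp(stats::rnorm(n, log(300), 1)))
    nightlight <- round(5 + 8 * log1p(population_density) +
                          stats::rnorm(n, 0, 3), 1)
    station_type <- sample(c("background", "industrial", "traffic"), n,
                           replace = TRUE, prob = c(0.6, 0.15, 0.25))
    area_type <- sample(c("rural", "suburban", "urban"), n,
                        replace = TRUE, prob = c(0.35, 0.30, 0.35))
    st <- station_table(sprintf("S%03d", seq_len(n)), lat, lon, altitude,
                        relative_altitude, population_density, nightlight,
                        station_type, area_type)
    attr(st, "xy_km") <- cbind(x = x, y = y)
    st
  })
}

# Seasonal cycle (ppb deviation) for a day-of-year vector; peaks in late July.
seasonal_cycle <- function(doy, amplitude) {
  amplitude * sin(2 * pi * (doy - 114) / 365.25)
}

# Diurnal cycle (ppb deviation) for an hour-of-day vector; peaks at 15:00.
diurnal_cycle <- function(hour, amplitude) {
  amplitude * sin(2 * pi * (hour - 9) / 24)
}

#' Simulate a complete concentration field
#'
#' Generates `value(s, t) = base + seasonal(doy) + diurnal(hour) + r(s, t) +
#' noise`, clipped at zero, where the residual field `r` is zero-mean
#' Gaussian with exponential spatial covariance
#' `cov(r_s, r_s') = field_sd^2 exp(-d(s, s') / spatial_corr_length)` and
#' stationary AR(1) temporal structure with coefficient `temporal_corr`.
#'
#' @param config A [synthetic_config()].
#' @param stations A station table from [simulate_stations()].
#' @return List with `panel` (complete [series_panel()], no gaps) and
#'   `drivers`: the latent seasonal and diurnal cycle vectors, the residual
#'   field matrix `field`, and the noise-free concentration matrix `clean`.
#' @export
simulate_field <- function(config, stations) {
  n_s <- nrow(stations); n_t <- config$n_hours
  timestamps <- seq(as.POSIXct("2011-01-01 00:00:00", tz = "UTC"),
                    by = "hour", length.out = n_t)
  lt <- as.POSIXlt(timestamps)
  seas <- seasonal_cycle(lt$yday + 1, config$seasonal_amplitude)
  diur <- diurnal_cycle(lt$hour, config$diurnal_amplitude)
  with_seed(sub_seed(config$seed, 2L), {
    if (config$field_sd > 0 && n_s >= 1) {
      xy <- attr(stations, "xy_km")
      D <- as.matrix(stats::dist(xy))
      Sigma <- config$field_sd^2 * exp(-D / config$spatial_corr_length)
      L <- t(chol(Sigma + diag(1e-9, n_s)))
      phi <- config$temporal_corr
      innov_scale <- sqrt(1 - phi^2)
      r <- matrix(0, n_s, n_t)
      r[, 1] <- L %*% stats::rnorm(n_s)
      if (n_t > 1) {
        Z <- L %*% matrix(stats::rnorm(n_s * (n_t - 1)), n_s)
        for (t in 2:n_t) r[, t] <- phi * r[, t - 1] + innov_scale * Z[, t - 1]
      }
    } else {
      r <- matrix(0, n_s, n_t)
    }
    clean <- config$base_level +
      matrix(seas, n_s, n_t, byrow = TRUE) +
      matrix(diur, n_s, n_t, byrow = TRUE) + r
    noise <- if (config$noise_sd > 0)
      matrix(stats::rnorm(n_s * n_t, 0, config$noise_sd), n_s, n_t)
    else matrix(0, n_s, n_t)
    vals <- pmax(clean + noise, 0)
    list(panel = series_panel(vals, stations$station_id, timestamps),
         drivers = list(seasonal = seas, diurnal = diur, field = r,
                        clean = clean))
  })
}

#' Derive the 19-feature auxiliary table from latent drivers
#'
#' Datetime features are exact functions of the timestamp. "Meteorological"
#' features are noisy affine transforms of the latent seasonal/diurnal cycles
#' and residual field, so a regressor has learnable signal with a known
#' ceiling. `reanalysis_o3` is a coarse surrogate: the cycles plus a
#' spatially smoothed (150 km kernel) version of the residual field, a
#' smooth spatial bias, and noise — it resolves the regional signal but not
#' the local station-scale residual, which therefore stays spatially
#' correlated in any feature-based model's errors (the structure the
#' correct-and-smooth step exploits). `reanalysis_no` is pure noise,
#' independent of the concentrations, so feature selection can drop
#' it. Static metadata are copied from the station table, with
#' `station_type`/`area_type` integer-encoded (background/industrial/traffic
#' and rural/suburban/urban as 1/2/3).
#'
#' @param stations Station table from [simulate_stations()].
#' @param timestamps Hourly `POSIXct` grid.
#' @param drivers Latent drivers from [simulate_field()].
#' @param seed Integer seed.
#' @return A [feature_table()] with one row per (station, hour),
#'   station-major.
#' @export
derive_features <- function(stations, timestamps, drivers, seed = 1L) {
  n_s <- nrow(stations); n_t <- length(timestamps)
  lt <- as.POSIXlt(timestamps)
  with_seed(sub_seed(seed, 3L), {
    n <- n_s * n_t
    # station-major expansion: rows = all hours of station 1, then station 2..
    seas <- rep(drivers$seasonal, times = n_s)
    diur <- rep(drivers$diurnal, times = n_s)
    r <- as.vector(t(drivers$field))       # [s-major] residual
    xy <- attr(stations, "xy_km")
    # coarse-resolution view of the residual field: kernel smoothing over
    # the network with a 150 km e-folding length (a reanalysis surrogate
    # resolves regional but not station-scale structure)
    D <- outer(seq_len(n_s), seq_len(n_s), function(i, j)
      station_distance(stations$latitude[i], stations$longitude[i],
                       stations$latitude[j], stations$longitude[j]))
    K <- exp(-D / 150)
    K <- K / rowSums(K)
    r_coarse <- as.vector(t(K %*% drivers$field))
    cycles <- as.vector(t(drivers$clean)) - r   # base + seasonal + diurnal
    f <- data.frame(
      hour_of_day = rep(lt$hour, times = n_s),
      day_of_week = rep(lt$wday, times = n_s),
      day_of_year = rep(lt$yday + 1L, times = n_s),
      temperature = 12 + 0.9 * seas + 0.6 * diur + 0.1 * r_coarse +
        stats::rnorm(n, 0, 1.5),
      relative_humidity = pmin(pmax(70 - 1.2 * diur - 0.2 * r_coarse +
                                      stats::rnorm(n, 0, 5), 5), 100),
      cloud_cover = pmin(pmax(0.6 - 0.015 * diur - 0.01 * seas +
                                stats::rnorm(n, 0, 0.2), 0), 1),
      pbl_height = pmax(500 + 35 * diur + 12 * seas + 3 * r_coarse +
                          stats::rnorm(n, 0, 100), 50),
      wind_u = 2 + stats::rnorm(n, 0, 2.5),
      wind_v = 0.5 + stats::rnorm(n, 0, 2.5),
      reanalysis_o3 = pmax(cycles + r_coarse +
                             rep(3 * sin(2 * pi * xy[, 1] / max(xy[, 1], 1)),
                                 each = n_t) + stats::rnorm(n, 0, 2), 0),
      reanalysis_no = stats::rnorm(n, 2, 1),
      reanalysis_no2 = pmax(10 - 0.5 * diur - 0.1 * r_coarse +
                              stats::rnorm(n, 0, 2), 0),
      emissions_nox = pmax(rep(2 * log1p(stations$population_density),
                               each = n_t) - 0.05 * seas +
                             stats::rnorm(n, 0, 0.5), 0),
      altitude = rep(stations$altitude, each = n_t),
      relative_altitude = rep(stations$relative_altitude, each = n_t),
      population_density = rep(stations$population_density, each = n_t),
      nightlight = rep(stations$nightlight, each = n_t),
      station_type = rep(match(stations$station_type,
                               c("background", "industrial", "traffic")),
                         each = n_t),
      area_type = rep(match(stations$area_type,
                            c("rural", "suburban", "urban")), each = n_t)
    )
    feature_table(rep(stations$station_id, each = n_t),
                  rep(timestamps, times = n_s), f)
  })
}

# Place a run of `len` hours in a logical free-mask (TRUE = free), requiring
# a 1-hour separation buffer on both sides (clipped at the edges). The start
# is drawn uniformly among all feasible positions; NA if none exists.
place_run <- function(free, len, sep = 1L, max_tries = NULL) {
  n <- length(free)
  if (len > n) return(NA_integer_)
  f <- as.integer(free)
  cs <- cumsum(c(0L, f))
  starts <- seq_len(n - len + 1L)
  lo <- pmax(1L, starts - sep)
  hi <- pmin(n, starts + len - 1L + sep)
  feasible <- starts[(cs[hi + 1L] - cs[lo]) == (hi - lo + 1L)]
  if (!length(feasible)) return(NA_integer_)
  feasible[sample.int(length(feasible), 1L)]
}

#' Inject the three gap patterns into a complete panel
#'
#' Removes approximately `missing_fraction` of all cells, split across the
#' three gap classes by `gap_mix`. Short single-station gaps draw lengths
#' uniformly from 1-5 h; long single-station gaps draw from a heavy-tailed
#' (log-uniform) distribution over 6 h to ~10 days; network-wide gaps draw
#' from a {3, 4, 18, 43} h mixture echoing observed simultaneous outages.
#' Placements are non-overlapping with a 1-hour separation so every injected
#' run stays maximal and [detect_gaps()] inverts the injection exactly.
#'
#' @param panel A complete [series_panel()] (no missing cells).
#' @param config A [synthetic_config()].
#' @return List with `panel` (gapped) and `inventory` (a `gap_inventory` of
#'   the injected records).
#' @export
inject_gaps <- function(panel, config) {
  stop_if_not(n_missing(panel) == 0, "inject_gaps needs a complete panel")
  v <- panel$values
  n_s <- nrow(v); n_t <- ncol(v)
  budget <- round(config$missing_fraction * length(v))
  if (budget == 0) {
    return(list(panel = panel, inventory = new_gap_inventory(
      data.frame(station_id = character(), start = as.POSIXct(character(), tz = "UTC"),
                 start_index = integer(), length = integer(), gap_class = character(),
                 bounded_left = logical(), bounded_right = logical()), n_s)))
  }
  with_seed(sub_seed(config$seed, 4L), {
    mix <- config$gap_mix
    recs <- list()
    hour_free <- rep(TRUE, n_t)          # hours not in a multi-station block
    row_free <- matrix(TRUE, n_s, n_t)   # per-station free cells
    # --- multi-station blocks ---
    multi_cells_target <- round(mix[3] * budget)
    multi_hours_target <- round(multi_cells_target / n_s)
    placed_hours <- 0L
    while (placed_hours < multi_hours_target) {
      len <- sample(c(3L, 4L, 18L, 43L), 1L, prob = c(0.4, 0.3, 0.2, 0.1))
      len <- min(len, multi_hours_target - placed_hours + 2L)
      s <- place_run(hour_free, len)
      if (is.na(s)) stop("could not place multi-station gaps without overlap",
                         call. = FALSE)
      hour_free[max(1L, s - 1L):min(n_t, s + len)] <- FALSE
      row_free[, max(1L, s - 1L):min(n_t, s + len)] <- FALSE
      v[, s:(s + len - 1L)] <- NA_real_
      recs[[length(recs) + 1L]] <- data.frame(
        station_id = "ALL", start = panel$timestamps[s], start_index = s,
        length = len, gap_class = "multi_station", stringsAsFactors = FALSE)
      placed_hours <- placed_hours + len
    }
    # --- single-station runs ---
    single_budget <- c(short = round(mix[1] * budget),
                       long = max(0L, budget - placed_hours * n_s -
                                    round(mix[1] * budget)))
    # cap the heavy tail well below the panel length so that equal-length
    # masked counterparts remain placeable between network-wide blocks
    lmax <- max(6L, min(1000L, n_t %/% 20L))
    draw_len <- function(cls) {
      if (cls == "short") sample(1:5, 1L)
      else max(6L, min(lmax, round(exp(stats::runif(1, log(6), log(lmax))))))
    }
    for (cls in c("long", "short")) {   # long first: harder to place
      placed <- 0L; fails <- 0L
      while (placed < single_budget[[cls]]) {
        len <- draw_len(cls)
        len <- if (cls == "short") min(len, single_budget[[cls]] - placed + 1L)
               else len
        st_i <- sample.int(n_s, 1L)
        s <- place_run(row_free[st_i, ], len, max_tries = 200L)
        if (is.na(s)) {
          fails <- fails + 1L
          if (fails > 500L) stop(sprintf(
            "could not place %s gaps without overlap (requested fraction infeasible)",
            cls), call. = FALSE)
          next
        }
        row_free[st_i, max(1L, s - 1L):min(n_t, s + len)] <- FALSE
        v[st_i, s:(s + len - 1L)] <- NA_real_
        recs[[length(recs) + 1L]] <- data.frame(
          station_id = panel$stations[st_i], start = panel$timestamps[s],
          start_index = s, length = len,
          gap_class = classify_gap(len, FALSE), stringsAsFactors = FALSE)
        placed <- placed + len
      }
    }
    out <- do.call(rbind, recs)
    out$bounded_left <- out$start_index > 1L
    out$bounded_right <- out$start_index + out$length - 1L < n_t
    out <- out[order(out$station_id != "ALL", out$station_id, out$start_index), ]
    rownames(out) <- NULL
    list(panel = series_panel(v, panel$stations, panel$timestamps),
         inventory = new_gap_inventory(out, n_s))
  })
}

#' Simulate a full synthetic study data set
#'
#' Convenience wrapper chaining [simulate_stations()], [simulate_field()],
#' [derive_features()] and [inject_gaps()].
#'
#' @param config A [synthetic_config()].
#' @return List with `stations`, `truth` (complete panel), `panel` (gapped),
#'   `features`, `inventory`, and `drivers`.
#' @export
simulate_network <- function(config = synthetic_config()) {
  stations <- simulate_stations(config)
  fld <- simulate_field(config, stations)
  features <- derive_features(stations, fld$panel$timestamps, fld$drivers,
                              seed = config$seed)
  gapped <- inject_gaps(fld$panel, config)
  list(stations = stations, truth = fld$panel, panel = gapped$panel,
       features = features, inventory = gapped$inventory,
       drivers = fld$drivers)
}
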