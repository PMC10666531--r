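# Base imputation models. Every imputer returns an `imputation` object and
# leaves observed cells bit-identical; `fitted` additionally carries the
# model's estimate at observed cells (where the method defines one), which
# the correct-and-smooth residual step consumes.

new_imputation <- function(panel, provenance, fitted, method) {
  structure(list(panel = panel, provenance = provenance, fitted = fitted,
                 method = method),
            class = "imputation")
}

#' @export
print.imputation <- function(x, ...) {
  filled <- table(x$provenance[!is.na(x$provenance)])
  cat(sprintf("imputation by '%s': %d cells filled", x$method,
              sum(!is.na(x$provenance) & x$provenance != "skipped")))
  if (length(filled)) {
    cat(" (", paste(sprintf("%s: %d", names(filled), filled), collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Impute the spatiotemporal mean
#'
#' Fills every gap cell with the mean of all available measurements in the
#' panel — the simplest statistical baseline, with zero variance across
#' imputed cells.
#'
#' @param panel A [series_panel()].
#' @return An `imputation` object: `panel` with gaps filled, `provenance`
#'   matrix naming the method per filled cell, and `fitted` estimates at all
#'   cells.
#' @export
impute_spatiotemporal_mean <- function(panel) {
  v <- panel$values
  stop_if_not(any(!is.na(v)), "panel has no observed values")
  m <- mean(v, na.rm = TRUE)
  prov <- matrix(NA_character_, nrow(v), ncol(v))
  prov[is.na(v)] <- "stm"
  out <- v; out[is.na(out)] <- m
  fitted <- matrix(m, nrow(v), ncol(v))
  new_imputation(series_panel(out, panel$stations, panel$timestamps),
                 prov, fitted, "stm")
}

#' Impute the time-dependent spatial mean
#'
#' Fills a gap at hour t with the mean over all stations observed at t; if no
#' station reports at t, the value of a per-hour reference series (e.g. a
#' network-mean reanalysis concentration) is used instead.
#'
#' @param panel A [series_panel()].
#' @param reference_series Numeric vector, one value per panel hour; only
#'   consulted at hours where no station is observed. May be `NULL` if no
#'   such hour exists.
#' @return An `imputation` object.
#' @export
impute_spatial_mean <- function(panel, reference_series = NULL) {
  v <- panel$values
  nobs <- colSums(!is.na(v))
  hmean <- colMeans(v, na.rm = TRUE)
  if (any(nobs == 0)) {
    stop_if_not(!is.null(reference_series) &&
                  length(reference_series) == ncol(v),
                "reference_series required: some hours have no observed station")
    hmean[nobs == 0] <- reference_series[nobs == 0]
  }
  prov <- matrix(NA_character_, nrow(v), ncol(v))
  prov[is.na(v)] <- ifelse(matrix(nobs == 0, nrow(v), ncol(v),
                                  byrow = TRUE)[is.na(v)], "sm_ref", "sm")
  fitted <- matrix(hmean, nrow(v), ncol(v), byrow = TRUE)
  out <- v; out[is.na(out)] <- fitted[is.na(v)]
  new_imputation(series_panel(out, panel$stations, panel$timestamps),
                 prov, fitted, "sm")
}

#' Linear interpolation of short bounded gaps
#'
#' Fills each per-station missing run strictly shorter than `L_t` hours by
#' the straight line through the observed values at the hours immediately
#' before and after the run. Runs of length >= `L_t`, and runs without an
#' observed endpoint on either side (panel edge or network-wide outage), are
#' left missing with provenance `"skipped"`.
#'
#' @param panel A [series_panel()].
#' @param L_t Threshold length in hours; runs with `length < L_t` are
#'   interpolated. The tuned value for hourly ozone is 6 (so gaps of up to
#'   5 h are covered).
#' @return A partial `imputation` object (`fitted` only at filled cells).
#' @export
interpolate_linear <- function(panel, L_t = 6) {
  stop_if_not(L_t >= 1, "L_t must be >= 1")
  v <- panel$values
  n_t <- ncol(v)
  prov <- matrix(NA_character_, nrow(v), n_t)
  fitted <- matrix(NA_real_, nrow(v), n_t)
  out <- v
  for (s in seq_len(nrow(v))) {
    miss <- is.na(v[s, ])
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      st <- starts[i]; en <- ends[i]; len <- en - st + 1L
      bounded <- st > 1L && en < n_t && !is.na(v[s, st - 1L]) &&
        !is.na(v[s, en + 1L])
      if (bounded && len < L_t) {
        y1 <- v[s, st - 1L]; y2 <- v[s, en + 1L]
        yy <- y1 + (y2 - y1) * (seq_len(len)) / (len + 1L)
        out[s, st:en] <- yy
        fitted[s, st:en] <- yy
        prov[s, st:en] <- "lin"
      } else {
        prov[s, st:en] <- "skipped"
      }
    }
  }
  new_imputation(series_panel(out, panel$stations, panel$timestamps),
                 prov, fitted, "lin")
}

#' Standardize features to zero mean and unit variance
#'
#' Centers and scales each feature column by the mean and sample standard
#' deviation (n-1 denominator) of a fitting subset of rows, so features on
#' different scales get equal weight in Euclidean distances.
#' Zero-variance features map to 0.
#'
#' @param features A [feature_table()] or numeric matrix/data frame of
#'   feature columns.
#' @param fit_rows Integer or logical index of the rows whose statistics
#'   define the transform (default: all rows).
#' @return List with `features` (standardized numeric matrix of all rows),
#'   `center`, and `scale`.
#' @export
standardize_features <- function(features, fit_rows = NULL) {
  df <- as.data.frame(features)
  df <- df[, setdiff(names(df), c("station_id", "timestamp")), drop = FALSE]
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(X))
  Xf <- X[fit_rows, , drop = FALSE]
  stop_if_not(nrow(Xf) >= 1, "fit_rows must be non-empty")
  ctr <- colMeans(Xf)
  scl <- apply(Xf, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- Inf  # zero-variance -> standardized 0
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  list(features = Z, center = ctr, scale = scl)
}

# Numeric feature matrix (19 columns) from a feature_table.
feature_matrix <- function(features) {
  as.matrix(as.data.frame(features)[, FEATURE_NAMES, drop = FALSE])
}

#' Nearest-neighbor imputation in feature space
#'
#' Fills each gap cell with the measured value of the labeled sample nearest
#' in standardized Euclidean feature space (19 dimensions for the canonical
#' auxiliary vector). Standardization statistics come from the labeled rows.
#' Ties are broken toward the smallest sample index.
#'
#' @param panel A [series_panel()].
#' @param features A [feature_table()] aligned with the panel (station-major
#'   row order).
#' @return An `imputation` object (`fitted` at labeled cells is the own
#'   observation, distance zero).
#' @export
impute_nearest_neighbor <- function(panel, features) {
  v <- panel$values
  n_s <- nrow(v); n_t <- ncol(v)
  X <- feature_matrix(features)
  stop_if_not(nrow(X) == n_s * n_t, "features must cover every (station, hour)")
  lab <- which(!is.na(t(v)))   # station-major cell index
  stop_if_not(length(lab) > 0, "no labeled samples")
  qry <- which(is.na(t(v)))
  out <- v
  prov <- matrix(NA_character_, n_s, n_t)
  fitted <- t(v)  # own value at labeled cells
  if (length(qry)) {
    Z <- standardize_features(X, fit_rows = lab)$features
    y_lab <- t(v)[lab]
    idx <- as.integer(as.character(
      class::knn1(Z[lab, , drop = FALSE], Z[qry, , drop = FALSE],
                  factor(seq_along(lab)))))
    fitted[qry] <- y_lab[idx]
    tv <- t(out); tv[qry] <- y_lab[idx]; out <- t(tv)
    prov[is.na(v)] <- "nn"
  }
  new_imputation(series_panel(out, panel$stations, panel$timestamps),
                 prov, t(fitted), "nn")
}

#' Nearest-neighbor hybrid imputation
#'
#' The best-performing statistical baseline for air-quality series: linear
#' interpolation ([interpolate_linear()]) for bounded gaps shorter than
#' `L_t`, multivariate nearest-neighbor interpolation
#' ([impute_nearest_neighbor()]) for all remaining gaps.
#'
#' @inheritParams impute_nearest_neighbor
#' @param L_t Threshold length in hours (tuned value 6).
#' @return An `imputation` object with provenance `"lin"` or `"nn"` per
#'   filled cell.
#' @export
impute_nnh <- function(panel, features, L_t = 6) {
  lin <- interpolate_linear(panel, L_t)
  res <- lin
  remaining <- is.na(lin$panel$values)
  if (any(remaining)) {
    nn <- impute_nearest_neighbor(panel, features)
    res$panel$values[remaining] <- nn$panel$values[remaining]
    res$provenance[remaining] <- "nn"
    res$fitted[remaining] <- nn$fitted[remaining]
  }
  res$method <- "nnh"
  res
}

#' Gridded reference field
#'
#' Container for a coarse gridded concentration field (a reanalysis
#' surrogate) with regular latitude/longitude axes and possibly coarser-than-
#' hourly time steps.
#'
#' @param latitude,longitude Axis vectors (grid-cell centers), degrees.
#' @param time `POSIXct` vector of reference time steps.
#' @param values Array `[latitude, longitude, time]`, ppb.
#' @return An object of class `reference_grid`.
#' @export
reference_grid <- function(latitude, longitude, time, values) {
  values <- array(values, dim = c(length(latitude), length(longitude),
                                  length(time)))
  structure(list(latitude = latitude, longitude = longitude,
                 time = as.POSIXct(time, tz = "UTC"), values = values),
            class = "reference_grid")
}

#' Impute from a gridded reference field
#'
#' Fills every gap cell with the reference value of the spatially
#' nearest grid cell (great-circle distance to cell centers) at the
#' temporally nearest reference step; temporal ties go to the earlier step.
#'
#' @param panel A [series_panel()].
#' @param stations A [station_table()] with the panel's stations.
#' @param grid A [reference_grid()] whose bounding box covers all stations.
#' @return An `imputation` object (`fitted` defined at every cell).
#' @export
impute_reference_field <- function(panel, stations, grid) {
  stop_if_not(all(stations$latitude >= min(grid$latitude) - 1e-9 &
                    stations$latitude <= max(grid$latitude) + 1e-9 &
                    stations$longitude >= min(grid$longitude) - 1e-9 &
                    stations$longitude <= max(grid$longitude) + 1e-9),
              "station outside reference grid bounding box")
  v <- panel$values
  si <- match(panel$stations, stations$station_id)
  cells <- expand.grid(la = seq_along(grid$latitude),
                       lo = seq_along(grid$longitude))
  # nearest grid cell per station
  near <- vapply(seq_len(nrow(v)), function(s) {
    d <- station_distance(stations$latitude[si[s]], stations$longitude[si[s]],
                          grid$latitude[cells$la], grid$longitude[cells$lo])
    which.min(d)
  }, integer(1))
  # nearest reference step per panel hour; ties toward the earlier step
  tt <- as.numeric(panel$timestamps); gt <- as.numeric(grid$time)
  tstep <- vapply(tt, function(x) {
    d <- abs(gt - x)
    which(d == min(d))[1]  # earlier step wins ties (gt sorted ascending)
  }, integer(1))
  fitted <- matrix(NA_real_, nrow(v), ncol(v))
  for (s in seq_len(nrow(v))) {
    fitted[s, ] <- grid$values[cbind(cells$la[near[s]], cells$lo[near[s]], tstep)]
  }
  prov <- matrix(NA_character_, nrow(v), ncol(v))
  prov[is.na(v)] <- "ref"
  out <- v; out[is.na(out)] <- fitted[is.na(v)]
  new_imputation(series_panel(out, panel$stations, panel$timestamps),
                 prov, fitted, "ref")
}
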