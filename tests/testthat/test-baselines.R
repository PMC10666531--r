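# Base imputers: means, linear interpolation, standardization,
# nearest-neighbor (with brute-force oracle), hybrid dispatch, reference
# field.

test_that("spatiotemporal mean fills every gap with the global mean", {
  p <- mk_panel(matrix(c(1, 2, NA, 3), 1))
  r <- impute_spatiotemporal_mean(p)
  expect_equal(r$panel$values[1, 3], 2)
  expect_equal(unname(r$provenance[1, 3]), "stm")
  # constant panel stays constant; zero variance across filled cells
  pc <- mk_panel(matrix(c(7, NA, 7, NA, 7, 7), 2))
  rc <- impute_spatiotemporal_mean(pc)
  filled <- rc$panel$values[is.na(pc$values)]
  expect_true(all(filled == 7))
  expect_equal(var(filled), 0)
  # observed cells bit-identical
  expect_identical(r$panel$values[!is.na(p$values)],
                   p$values[!is.na(p$values)])
  expect_error(impute_spatiotemporal_mean(mk_panel(matrix(NA_real_, 1, 2))),
               "no observed")
})

test_that("spatial mean uses per-hour means with a reference fallback", {
  v <- matrix(c(10, NA, NA,
                20, NA, 30), 2, 3, byrow = TRUE)
  p <- mk_panel(v)
  r <- impute_spatial_mean(p, reference_series = c(0, 37.5, 0))
  expect_equal(r$panel$values[2, 1], 20)  # untouched observed
  expect_equal(r$panel$values[1, 2], 37.5)  # no station observed at hour 2
  expect_equal(unname(r$provenance[1, 2]), "sm_ref")
  expect_equal(r$panel$values[1, 3], 30)  # mean of the single observed value
  # hour with observed values {10, 20} and one gap -> 15
  v2 <- matrix(c(10, 20, NA), 3, 1)
  r2 <- impute_spatial_mean(mk_panel(v2))
  expect_equal(r2$panel$values[3, 1], 15)
  # fully observed panel passes through unchanged
  p3 <- mk_panel(matrix(1:4, 2))
  expect_identical(impute_spatial_mean(p3)$panel$values, p3$values)
  # missing reference at a station-free hour is rejected
  expect_error(impute_spatial_mean(p), "reference_series")
})

test_that("linear interpolation is exact on lines and skips long/unbounded runs", {
  v <- matrix(c(10, NA, NA, 16), 1)
  r <- interpolate_linear(mk_panel(v), L_t = 6)
  expect_equal(r$panel$values[1, 2:3], c(12, 14))
  # constant endpoints
  v2 <- matrix(c(5, NA, NA, NA, 5), 1)
  expect_true(all(interpolate_linear(mk_panel(v2))$panel$values == 5))
  # a gap of length 6 is untouched at L_t = 6 (dispatch is length < L_t)
  v3 <- matrix(c(1, rep(NA, 6), 8, 1, NA, 1), 1)
  r3 <- interpolate_linear(mk_panel(v3), L_t = 6)
  expect_true(all(is.na(r3$panel$values[1, 2:7])))
  expect_true(all(r3$provenance[1, 2:7] == "skipped"))
  expect_equal(r3$panel$values[1, 10], 1)
  # unbounded run at the edge is skipped
  v4 <- matrix(c(NA, NA, 3, 4), 1)
  r4 <- interpolate_linear(mk_panel(v4), L_t = 6)
  expect_true(all(is.na(r4$panel$values[1, 1:2])))
  # exactness on an affine truth for arbitrary in-range gaps
  truth <- 2 + 0.5 * (0:49)
  v5 <- matrix(truth, 1)
  v5[1, c(5:8, 20, 33:34)] <- NA
  r5 <- interpolate_linear(mk_panel(v5), L_t = 6)
  expect_equal(r5$panel$values[1, ], truth, tolerance = 1e-12)
})

test_that("standardization uses fit-subset statistics with n-1 denominator", {
  X <- data.frame(a = c(0, 10, 2, 5), b = rep(3, 4))
  z <- standardize_features(X, fit_rows = 1:2)
  expect_equal(z$features[1:2, "a"], c(-1, 1) / sqrt(2))
  expect_equal(unname(z$scale["a"]), sd(c(0, 10)))
  expect_true(all(z$features[, "b"] == 0))  # zero variance -> 0
  zf <- standardize_features(X)
  expect_lt(abs(mean(zf$features[, "a"])), 1e-12)
})

test_that("nearest neighbor picks the closest labeled sample in feature space", {
  # 3 stations, 1 hour: datetime/static features identical, one informative
  # feature; labeled (f=0, y=5), (f=10, y=25); gap at f=2
  ts <- hourly(1)
  ft <- mk_features_1d(c("s1", "s2", "s3"), ts, c(0, 10, 2))
  p <- series_panel(matrix(c(5, 25, NA), 3, 1), c("s1", "s2", "s3"), ts)
  r <- impute_nearest_neighbor(p, ft)
  expect_equal(r$panel$values[3, 1], 5)
  # identical features to a labeled sample -> that sample's value
  ft2 <- mk_features_1d(c("s1", "s2", "s3"), ts, c(0, 10, 10))
  r2 <- impute_nearest_neighbor(p, ft2)
  expect_equal(r2$panel$values[3, 1], 25)
  expect_error(impute_nearest_neighbor(
    series_panel(matrix(NA_real_, 1, 1), "s1", ts),
    mk_features_1d("s1", ts, 0)), "no labeled")
})

test_that("nearest neighbor matches a brute-force oracle on 500 samples", {
  withr::local_seed(99)
  n_s <- 5; n_t <- 100
  ts <- hourly(n_t)
  temp <- rnorm(n_s * n_t, 10, 5)
  ft <- mk_features_1d(sprintf("s%d", 1:n_s), ts, temp)
  v <- matrix(runif(n_s * n_t, 10, 60), n_s, n_t)
  v[runif(n_s * n_t) < 0.2] <- NA
  p <- mk_panel(v)
  r <- impute_nearest_neighbor(p, ft)
  # oracle: exhaustive O(n^2) search over standardized features
  X <- as.matrix(as.data.frame(ft)[, feature_names()])
  tv <- t(v)
  lab <- which(!is.na(tv)); qry <- which(is.na(tv))
  Z <- standardize_features(X, fit_rows = lab)$features
  got <- t(r$panel$values)[qry]
  want <- vapply(qry, function(q) {
    d2 <- colSums((t(Z[lab, , drop = FALSE]) - Z[q, ])^2)
    tv[lab[which.min(d2)]]   # which.min takes the smallest index on ties
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("hybrid dispatches by gap length and reduces to NN at L_t = 1", {
  # one 2 h gap and one 48 h gap
  n_t <- 120
  truth <- 30 + 10 * sin(2 * pi * (0:(n_t - 1)) / 24)
  v <- matrix(truth, 1)
  v[1, 10:11] <- NA
  v[1, 40:87] <- NA
  p <- mk_panel(v)
  ft <- mk_features_1d("s1", p$timestamps, truth + rnorm(n_t, 0, 0.1))
  r <- impute_nnh(p, ft, L_t = 6)
  expect_true(all(r$provenance[1, 10:11] == "lin"))
  expect_true(all(r$provenance[1, 40:87] == "nn"))
  expect_equal(sum(r$provenance == "lin", na.rm = TRUE), 2)
  expect_equal(sum(r$provenance == "nn", na.rm = TRUE), 48)
  expect_false(anyNA(r$panel$values))
  # L_t = 1: pure nearest neighbor
  r1 <- impute_nnh(p, ft, L_t = 1)
  rn <- impute_nearest_neighbor(p, ft)
  expect_identical(r1$panel$values, rn$panel$values)
})

test_that("L_t tuning returns the RMSE-argmin over the candidate grid", {
  net <- memo("lt_net", simulate_network(
    synthetic_config(n_stations = 6, n_hours = 480, seed = 21)))
  a <- make_split(net$panel, net$inventory, seed = 3)
  masked <- apply_split(net$panel, a)
  val <- !is.na(a$roles) & a$roles == 1L
  fit <- tune_lt(masked, net$features, net$truth, val, candidates = c(2, 6, 12))
  expect_true(fit$L_t %in% c(2, 6, 12))
  expect_equal(unname(fit$L_t), as.numeric(names(which.min(fit$rmse))))
  # cross-check one candidate against a direct run
  direct <- impute_nnh(masked, net$features, L_t = 6)
  expect_equal(unname(fit$rmse[["6"]]),
               rmse(net$truth$values[val], direct$panel$values[val]),
               tolerance = 1e-12)
})

test_that("reference-field imputation picks nearest cell and earlier tie step", {
  ts <- hourly(7)
  # station s1 sits at a cell center of a 2x2 grid; s2 nearer to cell (1,1)
  st <- mk_stations(c(0, 10), c(0, 5))
  lat <- c(st$latitude[1], st$latitude[1] + 1)
  lon <- c(st$longitude[1], st$longitude[1] + 1.5)
  gtime <- ts[c(1, 3, 5, 7)]  # 2-hourly reference
  vals <- array(rep(c(11, 21, 12, 22), times = 4), c(2, 2, 4)) +
    rep(c(0, 100, 200, 300), each = 4)
  gr <- reference_grid(lat, lon, gtime, vals)
  v <- matrix(NA_real_, 2, 7); v[, 1] <- 50
  p <- series_panel(v, st$station_id, ts)
  r <- impute_reference_field(p, st, gr)
  # hour 2 (offset 1 h) ties between steps at 0 h and 2 h -> earlier wins
  expect_equal(r$panel$values[1, 2], 11)
  expect_equal(r$panel$values[1, 3], 111)   # exact match at the 2 h step
  expect_equal(r$panel$values[1, 4], 111)   # 3 h ties 2 h/4 h -> earlier
  # both stations are nearest to the (1, 1) cell given these axes
  expect_equal(r$panel$values[2, 2], 11)
  st_out <- mk_stations(c(500), c(500))
  expect_error(impute_reference_field(series_panel(matrix(1, 1, 7), "s1", ts),
                                      st_out, gr), "bounding box")
})
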