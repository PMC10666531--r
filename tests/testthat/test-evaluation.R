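# Metrics, gap-structure-preserving splitting, bucketed evaluation,
# repeated splits.

test_that("metric identities and worked values", {
  y <- c(1, 2, 3); yhat <- c(1, 2, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, yhat), 0.5)         # SSres 1, SStot 2
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_error(r_squared(c(2, 2), c(1, 2)), "variance")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(y, yhat), rmse(yhat, y))
  # RMSE^2 * n = SSres
  expect_equal(rmse(y, yhat)^2 * 3, sum((y - yhat)^2))

  expect_equal(willmott_d(y, y), 1)
  expect_equal(willmott_d(c(0, 2), c(0, 1)), 0.8)   # 1 - 1/5
  expect_equal(willmott_d(y, rep(mean(y), 3)), 0)
  withr::local_seed(30)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    expect_gte(willmott_d(a, b), 0)
    expect_lte(willmott_d(a, b), 1)
    expect_lte(r_squared(a, b), 1)
  }
})

test_that("split partitions observed cells and preserves gap histograms", {
  net <- default_net()
  a <- make_split(net$panel, net$inventory, seed = 9)
  roles <- a$roles
  obs <- !is.na(net$panel$values)
  # missing cells have no role; observed cells are train or masked
  expect_true(all(is.na(roles[!obs])))
  expect_true(all(roles[obs] %in% 0:2))
  # per-class length histogram of masked runs equals the real inventory's
  inv <- as.data.frame(net$inventory)
  for (cls in unique(inv$gap_class)) {
    expect_equal(sort(a$runs$length[a$runs$gap_class == cls]),
                 sort(inv$length[inv$gap_class == cls]))
  }
  # masked single-station runs are maximal: endpoints observed and unmasked
  single <- a$runs[a$runs$station_id != "ALL", ]
  for (i in seq_len(nrow(single))) {
    s <- match(single$station_id[i], net$panel$stations)
    st <- single$start_index[i]; en <- st + single$length[i] - 1L
    code <- if (single$role[i] == "validation") 1L else 2L
    expect_true(all(roles[s, st:en] == code))
    if (st > 1) expect_equal(roles[s, st - 1L], 0L)
    if (en < ncol(roles)) expect_equal(roles[s, en + 1L], 0L)
  }
  # validation and test each get about half the masked cells
  nv <- sum(roles == 1L, na.rm = TRUE); nt <- sum(roles == 2L, na.rm = TRUE)
  expect_lt(abs(nv - nt) / (nv + nt), 0.15)
})

test_that("splitting a gap-free panel falls back to a default inventory", {
  p <- mk_panel(matrix(50 + rnorm(30 * 2160, 0, 5), 30, 2160))
  a <- make_split(p, detect_gaps(p), seed = 2)
  frac_masked <- mean(a$roles %in% 1:2)
  expect_gt(frac_masked, 0.10)
  expect_lt(frac_masked, 0.20)
  expect_true(all(c("short_single", "long_single", "multi_station") %in%
                    a$runs$gap_class))
})

test_that("evaluation buckets by parent-run length with a pooled overall row", {
  # perfect imputation scores (1, 0, 1) everywhere
  net <- memo("lt_net", simulate_network(
    synthetic_config(n_stations = 6, n_hours = 480, seed = 21)))
  a <- make_split(net$panel, net$inventory, seed = 10)
  perfect <- structure(list(panel = net$truth,
                            provenance = matrix(NA_character_, 6, 480),
                            fitted = net$truth$values, method = "oracle"),
                       class = "imputation")
  rep1 <- evaluate(net$truth, perfect, a, role = "both")
  expect_true(all(abs(rep1$R2 - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(rep1$RMSE_ppb < 1e-12))
  expect_true(all(abs(rep1$d - 1) < 1e-12, na.rm = TRUE))
  # bucket sample counts sum to the masked-cell count
  expect_equal(sum(rep1$n[rep1$bucket != "overall"]),
               sum(a$roles %in% 1:2))

  # bucket boundary mapping for run lengths
  b <- ozimpute:::bucket_of(c(1, 2, 5, 6, 24, 167, 168))
  expect_equal(as.character(b), c("1 h", "2 h", "3-5 h", "6-23 h",
                                  "1-6 days", "1-6 days", ">=7 days"))
})

test_that("evaluation is invariant to station order", {
  net <- memo("lt_net", simulate_network(
    synthetic_config(n_stations = 6, n_hours = 480, seed = 21)))
  a <- make_split(net$panel, net$inventory, seed = 11)
  masked <- apply_split(net$panel, a)
  imp <- impute_nnh(masked, net$features, 6)
  r1 <- evaluate(net$truth, imp, a, role = "test")
  # permute stations consistently everywhere
  perm <- c(4, 2, 6, 1, 3, 5)
  pp <- function(p) series_panel(p$values[perm, ], p$stations[perm],
                                 p$timestamps)
  truth_p <- pp(net$truth)
  imp_p <- structure(list(panel = pp(imp$panel),
                          provenance = imp$provenance[perm, ],
                          fitted = imp$fitted[perm, ], method = imp$method),
                     class = "imputation")
  a_p <- a; a_p$roles <- a$roles[perm, ]
  r2 <- evaluate(truth_p, imp_p, a_p, role = "test")
  expect_equal(r1$RMSE_ppb, r2$RMSE_ppb, tolerance = 1e-12)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-12)
})

test_that("combined imputation is stable across ten resplits at study scale", {
  net <- default_net()
  g <- build_graph(net$stations, net$panel$timestamps)
  # tune the postprocessing once, on a split not used for scoring, then hold
  # hyperparameters fixed across the resplits
  a0 <- make_split(net$panel, net$inventory, seed = 99)
  m0 <- apply_split(net$panel, a0)
  val0 <- !is.na(a0$roles) & a0$roles == 1L
  rf0 <- impute_random_forest(m0, net$features,
                              rf_config(n_trees = 100, max_depth = 15,
                                        seed = 99))
  tuned <- tune_cs(rf0, m0, g, net$truth, val0)
  pipeline <- function(masked, assignment, seed) {
    combined_impute(masked, net$features, net$stations,
                    rf = rf_config(n_trees = 100, max_depth = 15,
                                   seed = seed),
                    cs = tuned$config, graph = g)
  }
  res <- repeat_splits(pipeline, net$panel, net$truth, net$inventory,
                       seeds = 1:10, role = "both")
  expect_equal(nrow(res$overall), 10L)
  expect_lt(max(res$overall$R2) - min(res$overall$R2), 0.05)
  expect_lt(max(res$overall$d) - min(res$overall$d), 0.05)
})

test_that("repeated splits report per-seed metrics with their range", {
  net <- memo("lt_net", simulate_network(
    synthetic_config(n_stations = 6, n_hours = 480, seed = 21)))
  pipeline <- function(masked, assignment, seed) {
    impute_nnh(masked, net$features, 6)
  }
  one <- repeat_splits(pipeline, net$panel, net$truth, net$inventory,
                       seeds = 4)
  expect_equal(nrow(one$overall), 1L)
  expect_equal(one$range$min, one$range$max)
  two <- repeat_splits(pipeline, net$panel, net$truth, net$inventory,
                       seeds = c(4, 5))
  expect_equal(two$overall[1, -1], one$overall[1, -1],
               ignore_attr = TRUE)  # deterministic given the seed
  expect_lte(two$range$min[two$range$metric == "R2"],
             two$range$max[two$range$metric == "R2"])
})
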