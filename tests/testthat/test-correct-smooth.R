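# Correct and smooth: residual initialization, propagation, both steps,
# end-to-end postprocessing, grid search.

test_that("residual initialization compares predictions to labels", {
  e <- residual_init(c(0, 0), c(1, NA))
  expect_equal(e, c(1, 0))
  expect_equal(residual_init(c(2, 3), c(2, 3)), c(0, 0))
  # mean residual over labeled nodes is minus the base bias
  withr::local_seed(20)
  y <- rnorm(50); base <- y + 0.7
  expect_equal(mean(residual_init(base, y)), -0.7, tolerance = 1e-12)
})

test_that("propagation: limits, 2-node arithmetic, linearity, bound", {
  S <- normalized_adjacency(two_node_graph())
  v0 <- c(1, 0)
  expect_identical(propagate(v0, S, alpha = 0, L = 10), v0)
  expect_identical(propagate(v0, S, alpha = 0.5, L = 0), v0)
  expect_equal(propagate(v0, S, 0.5, 1), c(0.5, 0.5))
  expect_equal(propagate(v0, S, 0.5, 2), c(0.75, 0.25))
  # linearity in v0
  withr::local_seed(21)
  rg <- random_graph(60, 0.1)
  Sg <- normalized_adjacency(rg$graph)
  u <- rnorm(60); w <- rnorm(60)
  lhs <- propagate(2 * u - 3 * w, Sg, 0.7, 15)
  rhs <- 2 * propagate(u, Sg, 0.7, 15) - 3 * propagate(w, Sg, 0.7, 15)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # geometric-series bound ||v^(l)|| <= ||v0|| / (1 - alpha)
  for (alpha in c(0.3, 0.9)) {
    for (L in c(1, 10, 50)) {
      vl <- propagate(u, Sg, alpha, L)
      expect_lte(sqrt(sum(vl^2)), sqrt(sum(u^2)) / (1 - alpha) + 1e-9)
    }
  }
})

test_that("propagation matches the dense oracle over many random graphs", {
  withr::local_seed(22)
  for (i in 1:25) {
    n <- sample(5:150, 1)
    rg <- random_graph(n, 0.12)
    Sg <- normalized_adjacency(rg$graph)
    dinv <- 1 / sqrt(rowSums(rg$dense))
    Sd <- diag(dinv) %*% rg$dense %*% diag(dinv)
    v0 <- rnorm(n)
    alpha <- runif(1, 0.1, 0.95)
    L <- sample(1:50, 1)
    vd <- v0
    for (l in seq_len(L)) vd <- (1 - alpha) * v0 + alpha * (Sd %*% vd)
    expect_lt(max(abs(propagate(v0, Sg, alpha, L) - as.vector(vd))), 1e-10)
  }
})

test_that("correct step: gamma limits and 2-node arithmetic", {
  S <- normalized_adjacency(two_node_graph())
  base <- c(0, 0); labels <- c(1, NA)
  expect_equal(correct(base, labels, S, cs_config(gamma = 0)), base)
  # L1 = 0: unlabeled nodes keep the base prediction
  c0 <- correct(base, labels, S, cs_config(L1 = 0, gamma = 1))
  expect_equal(c0[2], 0)
  cc <- correct(base, labels, S, cs_config(alpha1 = 0.5, L1 = 1, gamma = 1))
  expect_equal(cc, c(0.5, 0.5))
  # autoscale: mean |correction| on unlabeled equals mean |e0| on labeled
  ca <- correct(base, labels, S,
                cs_config(alpha1 = 0.5, L1 = 1, scaling_mode = "autoscale"))
  expect_equal(abs(ca[2] - base[2]), 1)  # sigma = |1 - 0| = 1
})

test_that("smooth step: limits, 2-node arithmetic, constant invariance", {
  S <- normalized_adjacency(two_node_graph())
  labels <- c(1, NA)
  corrected <- c(0.9, 0.5)
  g0 <- c(1, 0.5)  # labels override corrected on labeled nodes
  expect_equal(smooth_labels(corrected, labels, S, cs_config(alpha2 = 0)), g0)
  sm <- smooth_labels(corrected, labels, S,
                      cs_config(alpha2 = 0.5, L2 = 1))
  expect_equal(sm, c(0.75, 0.75))
  # a constant vector on a self-loop-free regular graph stays constant
  ring <- local({
    n <- 8
    A <- Matrix::sparseMatrix(i = c(1:n, 1:n),
                              j = c(c(2:n, 1), c(n, 1:(n - 1))),
                              x = rep(1, 2 * n), dims = c(n, n))
    list(A = A, degrees = Matrix::rowSums(A))
  })
  Sr <- normalized_adjacency(ring)
  const <- rep(3.3, 8)
  for (L in c(1, 5, 30)) {
    expect_equal(smooth_labels(const, rep(NA_real_, 8), Sr,
                               cs_config(alpha2 = 0.8, L2 = L)),
                 const, tolerance = 1e-12)
  }
})

test_that("end-to-end postprocessing touches only gap cells and helps stm", {
  net <- memo("cs_net", simulate_network(
    synthetic_config(n_stations = 10, n_hours = 720, seed = 31)))
  g <- memo("cs_graph", build_graph(net$stations, net$panel$timestamps))
  # a gap-free panel passes through unchanged
  full <- net$truth
  full_imp <- impute_spatiotemporal_mean(full)
  out <- correct_and_smooth(full_imp, full, g, cs_config())
  expect_identical(out$panel$values, full$values)

  a <- make_split(net$panel, net$inventory, seed = 5)
  masked <- apply_split(net$panel, a)
  stm <- impute_spatiotemporal_mean(masked)
  cs <- correct_and_smooth(stm, masked, g, cs_config())
  obs <- !is.na(masked$values)
  expect_identical(cs$panel$values[obs], masked$values[obs])
  held <- !is.na(a$roles) & a$roles > 0L
  expect_lt(rmse(net$truth$values[held], cs$panel$values[held]),
            rmse(net$truth$values[held], stm$panel$values[held]))
  # base result with uncovered gap cells is rejected
  lin <- interpolate_linear(masked, 6)
  expect_error(correct_and_smooth(lin, masked, g), "coverage|empty")
})

test_that("an isolated station receives corrections via temporal edges only", {
  # station 3 is 500 km away: no spatial neighbors
  st <- mk_stations(c(0, 20, 500))
  n_t <- 72
  ts <- hourly(n_t)
  v <- matrix(rep(30 + 10 * sin(2 * pi * (0:(n_t - 1)) / 24), each = 3), 3)
  v[3, 30:49] <- NA   # 20 h gap at the isolated station
  p <- series_panel(v, st$station_id, ts)
  g <- build_graph(st, ts)
  # graph reachability: no edges from station 3 to stations 1-2
  blk <- g$A[2 * n_t + 1:n_t, 1:(2 * n_t)]
  expect_equal(length(blk@x), 0L)
  stm <- impute_spatiotemporal_mean(p)
  cs <- correct_and_smooth(stm, p, g, cs_config())
  # the gap does receive corrections (through temporal edges)
  expect_false(isTRUE(all.equal(cs$panel$values[3, 30:49],
                                stm$panel$values[3, 30:49])))
  # and they match a run on the isolated station's own single-station graph
  # with the identical base prediction (the component is disconnected, so
  # propagation cannot differ)
  p_iso <- series_panel(v[3, , drop = FALSE], st$station_id[3], ts)
  g_iso <- build_graph(st[3, ], ts)
  base_iso <- structure(list(
    panel = series_panel(stm$panel$values[3, , drop = FALSE],
                         st$station_id[3], ts),
    provenance = stm$provenance[3, , drop = FALSE],
    fitted = stm$fitted[3, , drop = FALSE], method = "stm"),
    class = "imputation")
  cs_iso <- correct_and_smooth(base_iso, p_iso, g_iso, cs_config())
  expect_equal(cs$panel$values[3, ], cs_iso$panel$values[1, ],
               tolerance = 1e-10)
})

test_that("grid search returns the validation argmin and never loses to base", {
  net <- memo("cs_net", simulate_network(
    synthetic_config(n_stations = 10, n_hours = 720, seed = 31)))
  g <- memo("cs_graph", build_graph(net$stations, net$panel$timestamps))
  a <- make_split(net$panel, net$inventory, seed = 6)
  masked <- apply_split(net$panel, a)
  val <- !is.na(a$roles) & a$roles == 1L
  stm <- impute_spatiotemporal_mean(masked)
  fit <- tune_cs(stm, masked, g, net$truth, val)
  expect_lte(min(fit$rmse), fit$base_rmse)  # grid contains do-nothing
  expect_equal(which.min(fit$rmse), which(vapply(
    cs_default_grid(), identical, logical(1), fit$config)))
  # singleton grid returns that config
  single <- tune_cs(stm, masked, g, net$truth, val,
                    grid = list(cs_config(gamma = 0.5)))
  expect_identical(single$config, cs_config(gamma = 0.5))
  # grid scores match direct correct_and_smooth runs
  cfg <- cs_default_grid()[[4]]
  direct <- correct_and_smooth(stm, masked, g, cfg)
  expect_equal(unname(fit$rmse[4]),
               rmse(net$truth$values[val], direct$panel$values[val]),
               tolerance = 1e-10)
})
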