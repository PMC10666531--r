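# The 10-seed method-ranking experiment at the study's synthetic scale
# (30 stations x 2160 h, 15% missing, default gap mix). Computed once and
# memoized; several acceptance checks read from it.
#
# Desk-scale forest configuration: 100 trees at the tuned depth of 15.

ranking_methods <- c("lin", "stm", "sm", "nn", "rf",
                     "stm+cs", "sm+cs", "nn+cs", "rf+cs")

run_ranking_seed <- function(seed) {
  cfg <- synthetic_config(seed = seed)
  net <- simulate_network(cfg)
  assignment <- make_split(net$panel, net$inventory, seed = seed)
  masked <- apply_split(net$panel, assignment)
  graph <- build_graph(net$stations, net$panel$timestamps)
  roles <- assignment$roles
  val <- !is.na(roles) & roles == 1L
  n_s <- nrow(masked$values); n_t <- ncol(masked$values)

  # masked-cell index sets by gap category; short/long/overall use test
  # cells, the day-scale sets pool both masked roles for sample size
  all_runs <- assignment$runs
  cells_of <- function(sel_runs) {
    idx <- lapply(seq_len(nrow(sel_runs)), function(i) {
      run <- sel_runs[i, ]
      hrs <- run$start_index:(run$start_index + run$length - 1L)
      code <- if (run$role == "validation") 1L else 2L
      if (run$station_id == "ALL") {
        w <- which(roles[, hrs, drop = FALSE] == code, arr.ind = TRUE)
        cbind(w[, 1], hrs[w[, 2]])
      } else {
        cbind(match(run$station_id, masked$stations), hrs)
      }
    })
    do.call(rbind, idx)
  }
  tst <- all_runs[all_runs$role == "test", ]
  sets <- list(
    short = cells_of(tst[tst$gap_class == "short_single", ]),
    long = cells_of(tst[tst$gap_class == "long_single", ]),
    # day-scale gaps (>= 24 h), both masked roles: the isolated vs
    # network-wide contrast of correct-and-smooth is measured here
    long_days = cells_of(all_runs[all_runs$gap_class == "long_single" &
                                    all_runs$length >= 24, ]),
    multi_days = cells_of(all_runs[all_runs$gap_class == "multi_station" &
                                     all_runs$length >= 24, ]),
    overall = which(roles == 2L, arr.ind = TRUE))

  # reanalysis surrogate fallback for hours without any observation
  f <- as.data.frame(net$features)
  ref_series <- rowMeans(matrix(f$reanalysis_o3, n_t, n_s))

  bases <- list(
    stm = impute_spatiotemporal_mean(masked),
    sm = impute_spatial_mean(masked, ref_series),
    nn = impute_nearest_neighbor(masked, net$features),
    rf = impute_random_forest(masked, net$features,
                              rf_config(n_trees = 100, max_depth = 15,
                                        seed = seed)))
  results <- bases
  for (b in names(bases)) {
    tuned <- tune_cs(bases[[b]], masked, graph, net$truth, val)
    results[[paste0(b, "+cs")]] <-
      correct_and_smooth(bases[[b]], masked, graph, tuned$config)
  }
  results$lin <- interpolate_linear(masked, 6)

  score <- function(result, idx) {
    got <- result$panel$values[idx]
    ok <- !is.na(got)   # lin covers only its branch
    if (!any(ok)) return(NA_real_)
    rmse(net$truth$values[idx][ok], got[ok])
  }
  out <- expand.grid(method = ranking_methods, set = names(sets),
                     stringsAsFactors = FALSE)
  out$rmse <- mapply(function(m, s) score(results[[m]], sets[[s]]),
                     out$method, out$set)
  out$covered <- mapply(function(m, s)
    mean(!is.na(results[[m]]$panel$values[sets[[s]]])), out$method, out$set)
  out$seed <- seed
  out
}

ranking_experiment <- function(seeds = 1:10) {
  memo("ranking_experiment",
       do.call(rbind, lapply(seeds, run_ranking_seed)))
}

rank_mean <- function(rk, set_name) {
  agg <- aggregate(rmse ~ method, data = rk[rk$set == set_name, ], FUN = mean)
  stats::setNames(agg$rmse, agg$method)
}
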