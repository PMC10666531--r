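# Evaluation: the three metrics, gap-structure-preserving splitting,
# per-gap-class report tables, and repeated-split robustness.

#' Coefficient of determination
#'
#' `R2 = 1 - SSres / SStot`, the proportion of variance in the truth
#' explained by the imputation; at most 1, possibly negative, and exactly 0
#' for a constant imputation at the truth mean.
#'
#' @param truth,imputed Numeric vectors of equal length.
#' @return Unitless scalar.
#' @export
r_squared <- function(truth, imputed) {
  stop_if_not(length(truth) >= 2, "need at least 2 values")
  stop_if_not(length(truth) == length(imputed), "length mismatch")
  sstot <- sum((truth - mean(truth))^2)
  stop_if_not(sstot > 0, "truth variance is zero")
  1 - sum((truth - imputed)^2) / sstot
}

#' Root-mean-square error (ppb)
#'
#' @inheritParams r_squared
#' @return RMSE in the units of the inputs; 0 for perfect agreement.
#' @export
rmse <- function(truth, imputed) {
  stop_if_not(length(truth) >= 1 && length(truth) == length(imputed),
              "need equal-length non-empty vectors")
  sqrt(mean((truth - imputed)^2))
}

#' Willmott's index of agreement
#'
#' `d = 1 - sum((y - yhat)^2) / sum((|yhat - ybar| + |y - ybar|)^2)` with
#' `ybar` the truth mean; bounded in `[0, 1]`, 1 for error-free predictions,
#' 0 for a constant imputation at the truth mean.
#'
#' @inheritParams r_squared
#' @return Unitless scalar in `[0, 1]`.
#' @export
willmott_d <- function(truth, imputed) {
  stop_if_not(length(truth) >= 2 && length(truth) == length(imputed),
              "need >= 2 pairs of equal length")
  ybar <- mean(truth)
  denom <- sum((abs(imputed - ybar) + abs(truth - ybar))^2)
  stop_if_not(denom > 0, "degenerate inputs: zero potential error")
  1 - sum((truth - imputed)^2) / denom
}

# Gap-length evaluation buckets (hours), shared by single- and multi-station
# scopes.
bucket_of <- function(length) {
  cut(length, breaks = c(0, 1, 2, 5, 23, 167, Inf),
      labels = c("1 h", "2 h", "3-5 h", "6-23 h", "1-6 days", ">=7 days"))
}

#' Gap-structure-preserving train/validation/test split
#'
#' Partitions the observed cells of a panel: for every real gap record one
#' counterpart run of equal length and class is masked at a uniformly random
#' feasible position (single-station counterparts at a random station;
#' network-wide counterparts at hour runs clear of real network-wide blocks,
#' masking the cells observed there), alternately assigned to the validation and test sets so each receives
#' half the masked cells. Counterpart runs keep a 1-hour separation from
#' real gaps and from each other, so masked runs stay maximal and their
#' per-class length histogram matches the real inventory exactly. All
#' remaining observed cells are training cells; with 15% genuinely missing
#' this yields the 70 / 7.5 / 7.5 / 15 accounting of all cells.
#'
#' @param panel A gapped [series_panel()].
#' @param inventory Its `gap_inventory` ([detect_gaps()]). For a gap-free
#'   panel, a default inventory is generated from [synthetic_config()]'s
#'   gap mix and 15% budget.
#' @param seed Integer seed.
#' @param max_station_tries Placement retries before giving up.
#' @return A `split_assignment`: list with `roles` (integer matrix: 0 train,
#'   1 validation-masked, 2 test-masked, `NA` missing) and `runs` (data
#'   frame of masked counterpart runs).
#' @export
make_split <- function(panel, inventory = NULL, seed = 1L,
                       max_station_tries = 200L) {
  v <- panel$values
  n_s <- nrow(v); n_t <- ncol(v)
  if (is.null(inventory)) inventory <- detect_gaps(panel)
  if (nrow(inventory) == 0) {
    cfg <- synthetic_config(n_stations = n_s, n_hours = n_t, seed = seed)
    dummy <- series_panel(matrix(1, n_s, n_t), panel$stations,
                          panel$timestamps)
    inventory <- inject_gaps(dummy, cfg)$inventory
  }
  with_seed(sub_seed(seed, 5L), {
    roles <- matrix(0L, n_s, n_t)
    roles[is.na(v)] <- NA_integer_
    # free masks: observed, unmasked, with separation bookkeeping
    row_free <- !is.na(v)
    # hour-level mask for network-wide counterparts: keep clear of real
    # network-wide blocks (with 1 h separation)
    hour_free <- rep(TRUE, n_t)
    inv0 <- as.data.frame(inventory)
    for (i in which(inv0$gap_class == "multi_station")) {
      st <- inv0$start_index[i]; en <- st + inv0$length[i] - 1L
      hour_free[max(1L, st - 1L):min(n_t, en + 1L)] <- FALSE
    }
    runs <- list()
    assign_roles <- function(recs) {
      # greedy cell-count balancing within class, longest first, so the two
      # masked sets receive about half the cells each
      recs <- recs[order(-recs$length), , drop = FALSE]
      tot <- c(validation = 0, test = 0)
      recs$role <- vapply(recs$length, function(len) {
        pick <- if (tot[["validation"]] <= tot[["test"]]) "validation" else "test"
        tot[[pick]] <<- tot[[pick]] + len
        pick
      }, character(1))
      recs
    }
    inv <- as.data.frame(inventory)
    for (cls in c("multi_station", "long_single", "short_single")) {
      recs <- inv[inv$gap_class == cls, , drop = FALSE]
      if (nrow(recs) == 0) next
      recs <- assign_roles(recs)
      for (i in seq_len(nrow(recs))) {
        len <- recs$length[i]
        code <- if (recs$role[i] == "validation") 1L else 2L
        if (cls == "multi_station") {
          # place on hours free of real or masked network-wide blocks; the
          # observed cells in those hours are masked (already-missing cells
          # stay missing and are never scored)
          s <- place_run(hour_free, len)
          stop_if_not(!is.na(s),
                      "could not place a network-wide masked counterpart")
          hrs <- s:(s + len - 1L)
          obs <- !is.na(v[, hrs, drop = FALSE]) & row_free[, hrs, drop = FALSE]
          roles[, hrs][obs] <- code
          hour_free[max(1L, s - 1L):min(n_t, s + len)] <- FALSE
          row_free[, max(1L, s - 1L):min(n_t, s + len)] <- FALSE
          runs[[length(runs) + 1L]] <- data.frame(
            station_id = "ALL", start_index = s, length = len,
            gap_class = cls, role = recs$role[i], stringsAsFactors = FALSE)
        } else {
          placed <- FALSE
          for (st_i in sample.int(n_s)) {   # random station order, exhaustive
            s <- place_run(row_free[st_i, ], len)
            if (!is.na(s)) {
              roles[st_i, s:(s + len - 1L)] <- code
              row_free[st_i, max(1L, s - 1L):min(n_t, s + len)] <- FALSE
              runs[[length(runs) + 1L]] <- data.frame(
                station_id = panel$stations[st_i], start_index = s,
                length = len, gap_class = cls, role = recs$role[i],
                stringsAsFactors = FALSE)
              placed <- TRUE
              break
            }
          }
          stop_if_not(placed, sprintf(
            "could not place a %d h masked counterpart (class %s) without overlap",
            len, cls))
        }
      }
    }
    runs <- do.call(rbind, runs)
    rownames(runs) <- NULL
    structure(list(roles = roles, runs = runs, seed = seed),
              class = "split_assignment")
  })
}

#' @export
print.split_assignment <- function(x, ...) {
  total <- length(x$roles)
  counts <- c(train = sum(x$roles == 0L, na.rm = TRUE),
              validation = sum(x$roles == 1L, na.rm = TRUE),
              test = sum(x$roles == 2L, na.rm = TRUE),
              missing = sum(is.na(x$roles)))
  cat("split_assignment:\n")
  for (nm in names(counts)) {
    cat(sprintf("  %s: %d cells (%.1f%%)\n", nm, counts[[nm]],
                100 * counts[[nm]] / total))
  }
  invisible(x)
}

#' Apply a split: mask validation/test cells as missing
#'
#' @param panel The gapped panel used in [make_split()].
#' @param assignment A `split_assignment`.
#' @param roles Which roles to mask (default both masked sets).
#' @return A [series_panel()] with the selected cells set missing.
#' @export
apply_split <- function(panel, assignment, roles = c(1L, 2L)) {
  v <- panel$values
  v[assignment$roles %in% roles] <- NA_real_
  series_panel(v, panel$stations, panel$timestamps)
}

#' Evaluate an imputation on masked cells, per gap-class bucket
#'
#' Pools the masked cells whose parent counterpart run falls in each
#' length bucket (1 h, 2 h, 3-5 h, 6-23 h, 1-6 days, >= 7 days; single- and
#' multi-station scopes separately) and computes R2, RMSE (ppb) and
#' Willmott's d per bucket, plus an overall row over all masked cells of
#' the requested role.
#'
#' @param truth Complete truth panel.
#' @param result An `imputation` covering all masked cells.
#' @param assignment A `split_assignment` on the same panel.
#' @param role `"test"`, `"validation"`, or `"both"`.
#' @return An `eval_report` data frame with columns `scope`, `bucket`, `n`,
#'   `R2`, `RMSE_ppb`, `d`.
#' @export
evaluate <- function(truth, result, assignment, role = "test") {
  v_true <- truth$values
  v_imp <- result$panel$values
  n_s <- nrow(v_true)
  want <- switch(role, test = "test", validation = "validation",
                 both = c("validation", "test"),
                 stop("role must be test, validation or both"))
  runs <- assignment$runs[assignment$runs$role %in% want, , drop = FALSE]
  rows <- list()
  cells_y <- list(); cells_yhat <- list()
  for (i in seq_len(nrow(runs))) {
    run <- runs[i, ]
    hrs <- run$start_index:(run$start_index + run$length - 1L)
    if (run$station_id == "ALL") {
      # only cells actually masked (observed before masking) are scored
      code <- if (run$role == "validation") 1L else 2L
      sel <- which(assignment$roles[, hrs, drop = FALSE] == code,
                   arr.ind = TRUE)
      idx <- cbind(sel[, 1], hrs[sel[, 2]])
    } else {
      idx <- cbind(match(run$station_id, truth$stations), hrs)
    }
    y <- v_true[idx]; yhat <- v_imp[idx]
    stop_if_not(!anyNA(yhat), "imputation leaves masked cells uncovered")
    scope <- if (run$station_id == "ALL") "multi" else "single"
    rows[[i]] <- data.frame(scope = scope,
                            bucket = as.character(bucket_of(run$length)),
                            y = y, yhat = yhat, stringsAsFactors = FALSE)
  }
  all_cells <- do.call(rbind, rows)
  metr <- function(df) {
    data.frame(n = nrow(df),
               R2 = if (nrow(df) >= 2 && stats::var(df$y) > 0)
                 r_squared(df$y, df$yhat) else NA_real_,
               RMSE_ppb = rmse(df$y, df$yhat),
               d = if (nrow(df) >= 2) willmott_d(df$y, df$yhat) else NA_real_)
  }
  grp <- split(all_cells, list(all_cells$scope, all_cells$bucket), drop = TRUE)
  out <- do.call(rbind, lapply(names(grp), function(g) {
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    cbind(data.frame(scope = parts[1], bucket = parts[2],
                     stringsAsFactors = FALSE), metr(grp[[g]]))
  }))
  out <- rbind(out, cbind(data.frame(scope = "all", bucket = "overall",
                                     stringsAsFactors = FALSE),
                          metr(all_cells)))
  blev <- c("1 h", "2 h", "3-5 h", "6-23 h", "1-6 days", ">=7 days", "overall")
  out <- out[order(match(out$scope, c("single", "multi", "all")),
                   match(out$bucket, blev)), ]
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Imputation evaluation (pooled per gap-length bucket):\n")
  df <- as.data.frame(x)
  df$R2 <- round(df$R2, 3); df$RMSE_ppb <- round(df$RMSE_ppb, 3)
  df$d <- round(df$d, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Repeated data splits for robustness
#'
#' Re-runs split, imputation and evaluation for several seeds and reports
#' the per-split overall metrics with their min/max range.
#'
#' @param pipeline Function `(masked_panel, assignment, seed) -> imputation`.
#' @param panel Gapped panel.
#' @param truth Complete truth panel.
#' @param inventory Gap inventory of `panel` (or `NULL` to detect).
#' @param seeds Integer vector of split seeds (default 10 splits).
#' @param role Which masked cells to score (`"test"`, `"validation"`, or
#'   `"both"`).
#' @return List with `reports` (per seed), `overall` (data frame of overall
#'   metrics per seed), and `range` (min/max per metric).
#' @export
repeat_splits <- function(pipeline, panel, truth, inventory = NULL,
                          seeds = 1:10, role = "test") {
  if (is.null(inventory)) inventory <- detect_gaps(panel)
  reports <- list()
  overall <- NULL
  for (sd in seeds) {
    assignment <- make_split(panel, inventory, seed = sd)
    masked <- apply_split(panel, assignment)
    result <- pipeline(masked, assignment, sd)
    rep_i <- evaluate(truth, result, assignment, role = role)
    reports[[as.character(sd)]] <- rep_i
    ov <- rep_i[rep_i$bucket == "overall", c("R2", "RMSE_ppb", "d")]
    overall <- rbind(overall, cbind(data.frame(seed = sd), ov))
  }
  rng <- data.frame(
    metric = c("R2", "RMSE_ppb", "d"),
    min = c(min(overall$R2), min(overall$RMSE_ppb), min(overall$d)),
    max = c(max(overall$R2), max(overall$RMSE_ppb), max(overall$d)))
  list(reports = reports, overall = overall, range = rng)
}
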