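# Random-forest imputation: model fitting, depth tuning, forward feature
# selection, and the panel-level imputer. The forest itself is ranger's;
# this module owns the tuning procedures and the imputation surface.

#' Random-forest configuration
#'
#' @param n_trees Number of trees (>= 1). 500 is the reference
#'   configuration; scaled-down experiments may use fewer.
#' @param max_depth Maximum tree depth: `Inf` (or `NULL`) for unlimited,
#'   a positive integer to limit, or `0` for a root-only tree that predicts
#'   the training mean. The tuned value for the full ozone panel is 15.
#' @param seed Integer seed making fitting deterministic.
#' @param selected_features Character vector of feature names to use, or
#'   `NULL` (default) for every feature column present in the data.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, max_depth = Inf, seed = 1L,
                      selected_features = NULL) {
  if (is.null(max_depth)) max_depth <- Inf
  stop_if_not(n_trees >= 1, "n_trees must be >= 1")
  stop_if_not(max_depth >= 0, "max_depth must be >= 0, or Inf for unlimited")
  stop_if_not(is.null(selected_features) || length(selected_features) >= 1,
              "selected_features must be non-empty")
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 seed = as.integer(seed),
                 selected_features = selected_features),
            class = "rf_config")
}

#' Fit a random-forest regressor on auxiliary features
#'
#' Fits a bagged ensemble of depth-limited regression trees mapping the
#' auxiliary feature vector to concentration (ppb). Deterministic given
#' `config$seed`.
#'
#' @param features Data frame or matrix of feature columns (labeled rows).
#' @param labels Numeric measurements, one per row of `features`.
#' @param config An [rf_config()].
#' @return An object of class `rf_model` with `$oob` out-of-bag predictions
#'   on the training rows; use `predict()` to map new feature rows to ppb.
#' @export
fit_rf <- function(features, labels, config = rf_config()) {
  df <- as.data.frame(features)
  candidates <- setdiff(names(df), c("station_id", "timestamp"))
  keep <- if (is.null(config$selected_features)) candidates
          else intersect(config$selected_features, candidates)
  stop_if_not(length(keep) >= 1, "no selected features present in data")
  df <- df[, keep, drop = FALSE]
  ok <- !is.na(labels)
  stop_if_not(sum(ok) >= 2, "need at least 2 labeled samples")
  df <- df[ok, , drop = FALSE]; y <- labels[ok]
  if (config$max_depth == 0) {
    m <- structure(list(mean = mean(y), config = config,
                        feature_names = keep,
                        oob = rep(mean(y), length(y))),
                   class = "rf_model")
    return(m)
  }
  depth <- if (is.finite(config$max_depth)) as.integer(config$max_depth) else 0L
  fit <- ranger::ranger(y = y, x = df, num.trees = config$n_trees,
                        max.depth = depth, seed = config$seed,
                        num.threads = 1L, verbose = FALSE)
  structure(list(model = fit, config = config, feature_names = keep,
                 oob = fit$predictions),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  if (!is.null(object$mean)) return(rep(object$mean, nrow(df)))
  stats::predict(object$model, data = df, num.threads = 1L)$predictions
}

#' Impute gaps with a random forest
#'
#' Fits [fit_rf()] on the observed cells of the panel (features as inputs,
#' measurements as output) and predicts every gap cell. `fitted` values at
#' observed cells are the forest's out-of-bag predictions, giving the
#' correct-and-smooth residual step an honest error estimate.
#'
#' @param panel A [series_panel()].
#' @param features A [feature_table()] aligned with the panel.
#' @param config An [rf_config()].
#' @return An `imputation` object.
#' @export
impute_random_forest <- function(panel, features, config = rf_config()) {
  v <- panel$values
  n_s <- nrow(v); n_t <- ncol(v)
  X <- as.data.frame(features)[, FEATURE_NAMES]
  tv <- t(v)
  lab <- which(!is.na(tv)); qry <- which(is.na(tv))
  model <- fit_rf(X[lab, , drop = FALSE], tv[lab], config)
  fitted_t <- rep(NA_real_, length(tv))
  fitted_t[lab] <- model$oob
  if (length(qry)) {
    fitted_t[qry] <- pmax(predict(model, X[qry, , drop = FALSE]), 0)
    tv[qry] <- fitted_t[qry]
  }
  prov <- matrix(NA_character_, n_s, n_t)
  prov[is.na(v)] <- "rf"
  new_imputation(series_panel(t(tv), panel$stations, panel$timestamps),
                 prov, t(matrix(fitted_t, n_t, n_s)), "rf")
}

rmse_vec <- function(a, b) sqrt(mean((a - b)^2))

#' Tune the maximum tree depth
#'
#' Starting from unlimited depth and searching downward, returns the largest
#' depth at which the training and validation RMSE agree to within
#' `tolerance` (relative to the validation RMSE) — the point where the
#' forest stops overfitting. If no candidate satisfies the tolerance, the
#' depth minimizing the train/validation difference is returned with a
#' warning.
#'
#' @param features,labels Labeled data as in [fit_rf()].
#' @param split List with integer indices `train` and `validation`.
#' @param config Base [rf_config()] (its `max_depth` is ignored).
#' @param candidates Depths to try, descending; `Inf` = unlimited.
#' @param tolerance Relative train/validation RMSE agreement (default 2%).
#' @return The selected depth (possibly `Inf`).
#' @export
tune_depth <- function(features, labels, split, config = rf_config(),
                       candidates = c(Inf, 25, 20, 15, 12, 10, 8, 6, 5, 4, 3, 2, 1),
                       tolerance = 0.02) {
  df <- as.data.frame(features)
  diffs <- numeric(0)
  for (d in candidates) {
    cfg <- config; cfg$max_depth <- d
    m <- fit_rf(df[split$train, , drop = FALSE], labels[split$train], cfg)
    tr <- rmse_vec(predict(m, df[split$train, , drop = FALSE]),
                   labels[split$train])
    va <- rmse_vec(predict(m, df[split$validation, , drop = FALSE]),
                   labels[split$validation])
    rel <- abs(tr - va) / max(va, .Machine$double.eps)
    diffs <- c(diffs, rel)
    if (rel <= tolerance) return(d)
  }
  warning("no depth reached train/validation agreement; returning closest")
  candidates[which.min(diffs)]
}

#' Greedy forward feature selection
#'
#' Repeatedly adds the candidate feature whose addition most improves the
#' validation metric (RMSE by default, strictly), stopping when no addition
#' improves it. Deterministic given the config seed.
#'
#' @inheritParams tune_depth
#' @param metric `"rmse"` (minimized) or `"r2"` (maximized).
#' @return Character vector of selected feature names, in selection order.
#' @export
forward_feature_selection <- function(features, labels, split,
                                      config = rf_config(n_trees = 100),
                                      metric = c("rmse", "r2")) {
  metric <- match.arg(metric)
  df <- as.data.frame(features)
  candidates <- setdiff(names(df), c("station_id", "timestamp"))
  stop_if_not(length(candidates) >= 1, "no candidate features")
  score <- function(cols) {
    cfg <- config; cfg$selected_features <- cols
    m <- fit_rf(df[split$train, , drop = FALSE], labels[split$train], cfg)
    pred <- predict(m, df[split$validation, , drop = FALSE])
    truth <- labels[split$validation]
    if (metric == "rmse") rmse_vec(pred, truth) else -r_squared(truth, pred)
  }
  selected <- character(0)
  best <- Inf
  repeat {
    rest <- setdiff(candidates, selected)
    if (!length(rest)) break
    trial <- vapply(rest, function(f) score(c(selected, f)), numeric(1))
    if (min(trial) < best) {
      best <- min(trial)
      selected <- c(selected, rest[which.min(trial)])
    } else break
  }
  if (!length(selected)) selected <- candidates[1]
  selected
}

#' Tune the linear-interpolation threshold of the hybrid imputer
#'
#' Exhaustively evaluates candidate thresholds `L_t` (1 h steps) for
#' [impute_nnh()] against held-out truth on validation-masked cells and
#' returns the RMSE-argmin.
#'
#' @param panel Panel whose gaps include the validation-masked cells.
#' @param features Aligned [feature_table()].
#' @param truth Complete truth panel.
#' @param val_mask Logical matrix selecting validation cells.
#' @param candidates Integer thresholds to try.
#' @return List with `L_t` (selected) and `rmse` per candidate.
#' @export
tune_lt <- function(panel, features, truth, val_mask, candidates = 1:12) {
  scores <- vapply(candidates, function(lt) {
    imp <- impute_nnh(panel, features, L_t = lt)
    rmse_vec(imp$panel$values[val_mask], truth$values[val_mask])
  }, numeric(1))
  list(L_t = candidates[which.min(scores)],
       rmse = stats::setNames(scores, candidates))
}
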