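# Correct and smooth, adapted to regression: residual propagation over the
# spatiotemporal graph ("correct"), then label propagation ("smooth").
# Single output channel, no softmax.

#' Correct-and-smooth configuration
#'
#' @param alpha1 Residual-propagation mixing coefficient in `[0, 1)`.
#' @param L1 Residual-propagation iterations (>= 0).
#' @param alpha2 Label-propagation mixing coefficient in `[0, 1)`.
#' @param L2 Label-propagation iterations (>= 0).
#' @param gamma Fixed scale applied to the propagated error correction
#'   (>= 0); used in `fixed_gamma` mode.
#' @param scaling_mode `"fixed_gamma"` adds `gamma * E` to the base
#'   prediction; `"autoscale"` rescales the propagated errors so their mean
#'   absolute value on unlabeled nodes equals the mean absolute training
#'   residual, damping the influence of training nodes with the number of
#'   propagation hops.
#' @return A list of class `cs_config`.
#' @export
cs_config <- function(alpha1 = 0.8, L1 = 20L, alpha2 = 0.8, L2 = 20L,
                      gamma = 1, scaling_mode = c("fixed_gamma", "autoscale")) {
  scaling_mode <- match.arg(scaling_mode)
  stop_if_not(alpha1 >= 0 && alpha1 < 1, "alpha1 must be in [0, 1)")
  stop_if_not(alpha2 >= 0 && alpha2 < 1, "alpha2 must be in [0, 1)")
  stop_if_not(L1 >= 0 && L2 >= 0, "iteration counts must be >= 0")
  stop_if_not(gamma >= 0, "gamma must be >= 0")
  structure(list(alpha1 = alpha1, L1 = as.integer(L1), alpha2 = alpha2,
                 L2 = as.integer(L2), gamma = gamma,
                 scaling_mode = scaling_mode),
            class = "cs_config")
}

#' Initial residual vector of a base model
#'
#' `e0_k = y_k - yhat_k` on labeled nodes, 0 on unlabeled nodes.
#'
#' @param base Numeric node vector of base-model predictions (all nodes).
#' @param labels Numeric node vector of measurements, `NA` on unlabeled
#'   nodes.
#' @return Numeric node vector.
#' @export
residual_init <- function(base, labels) {
  e0 <- labels - base
  e0[is.na(e0)] <- 0
  e0
}

#' Iterative graph propagation
#'
#' Runs `v^(l+1) = (1 - alpha) * v0 + alpha * S v^(l)` starting from
#' `v^(0) = v0` and returns `v^(L)`. With `alpha = 0` or `L = 0` this is the
#' identity. Each iteration costs one sparse matrix-vector product.
#'
#' @param v0 Numeric node vector.
#' @param S Normalized adjacency operator from [normalized_adjacency()].
#' @param alpha Mixing coefficient in `[0, 1)`.
#' @param L Number of iterations (>= 0).
#' @return Numeric node vector.
#' @export
propagate <- function(v0, S, alpha, L) {
  stop_if_not(alpha >= 0 && alpha < 1, "alpha must be in [0, 1)")
  stop_if_not(L >= 0, "L must be >= 0")
  v <- v0
  if (alpha == 0 || L == 0) return(v0)
  for (l in seq_len(L)) v <- (1 - alpha) * v0 + alpha * as.vector(S %*% v)
  v
}

#' The "correct" step: residual propagation
#'
#' Propagates the base model's training residuals across the graph and adds
#' the resulting error correction to the base prediction. In `fixed_gamma`
#' mode the correction is `gamma * E`; in `autoscale` mode it is scaled so
#' that the mean absolute correction on unlabeled nodes equals the mean
#' absolute training residual.
#'
#' @param base Numeric node vector of base predictions.
#' @param labels Node vector of measurements (`NA` = unlabeled).
#' @param S Normalized adjacency operator.
#' @param config A [cs_config()].
#' @return Corrected node vector.
#' @export
correct <- function(base, labels, S, config = cs_config()) {
  e0 <- residual_init(base, labels)
  E <- propagate(e0, S, config$alpha1, config$L1)
  if (config$scaling_mode == "fixed_gamma") {
    base + config$gamma * E
  } else {
    labeled <- !is.na(labels)
    sigma <- mean(abs(e0[labeled]))
    denom <- mean(abs(E[!labeled]))
    s <- if (is.finite(denom) && denom > 0) sigma / denom else 0
    base + s * E
  }
}

#' The "smooth" step: label propagation
#'
#' Starts from the measurements on labeled nodes and the corrected
#' predictions on unlabeled nodes, then propagates, exploiting that
#' neighboring nodes (in space and time) carry similar concentrations.
#'
#' @param corrected Node vector of corrected predictions.
#' @inheritParams correct
#' @return Final smoothed node vector.
#' @export
smooth_labels <- function(corrected, labels, S, config = cs_config()) {
  g0 <- ifelse(is.na(labels), corrected, labels)
  propagate(g0, S, config$alpha2, config$L2)
}

# Node vector (station-major: k = (s-1)*n_hours + t) from a panel matrix.
panel_to_nodes <- function(values) as.vector(t(values))
nodes_to_panel <- function(v, n_s, n_t) t(matrix(v, n_t, n_s))

#' Correct-and-smooth postprocessing of a base imputation
#'
#' Assembles node vectors from the panel (labels = observed cells) and a
#' base imputation (predictions everywhere: `fitted` where defined,
#' otherwise the imputed/observed value), runs [correct()] then
#' [smooth_labels()] over the graph, and writes the smoothed values back to
#' the gap cells only; observed cells are untouched.
#'
#' @param base_result An `imputation` covering every gap cell of `panel`.
#' @param panel The gapped [series_panel()] the base model imputed.
#' @param graph An `st_graph` over the same stations and hours.
#' @param config A [cs_config()].
#' @return An object of class `cs_fit`, which is also an `imputation`:
#'   `panel` (postprocessed), `provenance` (base tag + `"+cs"`), `fitted`
#'   (smoothed node values as a matrix), plus the `config` used.
#' @export
correct_and_smooth <- function(base_result, panel, graph,
                               config = cs_config()) {
  v <- panel$values
  n_s <- nrow(v); n_t <- ncol(v)
  stop_if_not(graph$n_stations == n_s && graph$n_hours == n_t,
              "graph dimensions do not match panel")
  base_vals <- base_result$panel$values
  stop_if_not(!any(is.na(base_vals[is.na(v)])),
              "base_result leaves gap cells empty; correct-and-smooth needs full coverage")
  base_pred <- base_result$fitted
  base_pred[is.na(base_pred)] <- base_vals[is.na(base_pred)]
  labels <- panel_to_nodes(v)
  base_nodes <- panel_to_nodes(base_pred)
  S <- normalized_adjacency(graph)
  corrected <- correct(base_nodes, labels, S, config)
  smoothed <- smooth_labels(corrected, labels, S, config)
  sm <- nodes_to_panel(smoothed, n_s, n_t)
  out <- v
  out[is.na(v)] <- pmax(sm[is.na(v)], 0)
  prov <- base_result$provenance
  prov[is.na(v)] <- paste0(ifelse(is.na(prov[is.na(v)]), base_result$method,
                                  prov[is.na(v)]), "+cs")
  res <- new_imputation(series_panel(out, panel$stations, panel$timestamps),
                        prov, sm, paste0(base_result$method, "+cs"))
  res$config <- config
  class(res) <- c("cs_fit", class(res))
  res
}

#' @export
print.cs_fit <- function(x, ...) {
  cat(sprintf(
    "correct-and-smooth fit over base '%s' (alpha1=%.2f, L1=%d, alpha2=%.2f, L2=%d, %s%s)\n",
    sub("\\+cs$", "", x$method), x$config$alpha1, x$config$L1,
    x$config$alpha2, x$config$L2, x$config$scaling_mode,
    if (x$config$scaling_mode == "fixed_gamma")
      sprintf(", gamma=%.2f", x$config$gamma) else ""))
  NextMethod()
}

#' Default correct-and-smooth search grid
#'
#' A small validation grid including the do-nothing configuration, so grid
#' search can never select a postprocessing that hurts validation RMSE.
#'
#' @return List of [cs_config()] objects.
#' @export
cs_default_grid <- function() {
  grid <- list(cs_config(L1 = 0, L2 = 0, gamma = 0))  # do-nothing
  for (gamma in c(0, 0.5, 1)) {
    for (a2 in c(0.5, 0.8)) {
      grid[[length(grid) + 1L]] <- cs_config(alpha1 = 0.8, L1 = 20,
                                             alpha2 = a2, L2 = 20,
                                             gamma = gamma)
    }
  }
  for (a2 in c(0.5, 0.8)) {
    grid[[length(grid) + 1L]] <- cs_config(alpha1 = 0.8, L1 = 20,
                                           alpha2 = a2, L2 = 20,
                                           scaling_mode = "autoscale")
  }
  grid
}

#' Grid-search correct-and-smooth hyperparameters
#'
#' Exhaustively evaluates candidate configurations by RMSE on
#' validation-masked cells and returns the argmin (ties: first in grid
#' order). Propagated error vectors are cached across configurations that
#' share `alpha1`/`L1`, so the search costs little more than one propagation
#' per distinct setting.
#'
#' @param base_result Base `imputation` of `panel`.
#' @param panel Gapped panel (validation cells among its gaps).
#' @param graph An `st_graph`.
#' @param truth Complete truth panel (values at validation cells).
#' @param val_mask Logical matrix selecting validation cells.
#' @param grid List of [cs_config()] objects, default [cs_default_grid()].
#' @return List with `config` (selected), `rmse` (per grid point), and
#'   `base_rmse`.
#' @export
tune_cs <- function(base_result, panel, graph, truth, val_mask,
                    grid = cs_default_grid()) {
  stop_if_not(length(grid) >= 1, "grid must be non-empty")
  v <- panel$values
  n_s <- nrow(v); n_t <- ncol(v)
  base_vals <- base_result$panel$values
  base_pred <- base_result$fitted
  base_pred[is.na(base_pred)] <- base_vals[is.na(base_pred)]
  labels <- panel_to_nodes(v)
  base_nodes <- panel_to_nodes(base_pred)
  S <- normalized_adjacency(graph)
  labeled <- !is.na(labels)
  e0 <- residual_init(base_nodes, labels)
  truth_val <- truth$values[val_mask]
  E_cache <- list()
  scores <- vapply(grid, function(cfg) {
    key <- sprintf("%g_%d", cfg$alpha1, cfg$L1)
    if (is.null(E_cache[[key]])) {
      E_cache[[key]] <<- propagate(e0, S, cfg$alpha1, cfg$L1)
    }
    E <- E_cache[[key]]
    corrected <- if (cfg$scaling_mode == "fixed_gamma") {
      base_nodes + cfg$gamma * E
    } else {
      sigma <- mean(abs(e0[labeled]))
      denom <- mean(abs(E[!labeled]))
      base_nodes + (if (is.finite(denom) && denom > 0) sigma / denom else 0) * E
    }
    smoothed <- smooth_labels(corrected, labels, S, cfg)
    sm <- nodes_to_panel(smoothed, n_s, n_t)
    filled <- v
    filled[is.na(v)] <- pmax(sm[is.na(v)], 0)
    rmse_vec(filled[val_mask], truth_val)
  }, numeric(1))
  list(config = grid[[which.min(scores)]], rmse = scores,
       base_rmse = rmse_vec(base_vals[val_mask], truth_val))
}
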