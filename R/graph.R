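# Spatiotemporal station graph: one node per (station, hour), edges between
# nodes at most d_max km and t_max hours apart, weighted by a distance-decay
# kernel, stored once as a symmetric sparse adjacency matrix.

#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees (vectorized).
#' @return Distance in km.
#' @export
station_distance <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Distance-decay edge weight
#'
#' The default kernel weighting an edge by its spatial and temporal
#' separation: `w = 1 / ((1 + dx/d_max) * (1 + dt/t_max))`. It is maximal
#' (1) at zero separation and strictly decreasing in each argument. The
#' graph builder accepts any such kernel via its `kernel` argument.
#'
#' @param dx Spatial separation, km (must be `<= d_max`).
#' @param dt Temporal separation, hours (must be `<= t_max`).
#' @param d_max,t_max Edge thresholds (km, hours).
#' @return Weight in (0, 1].
#' @export
edge_weight <- function(dx, dt, d_max = 50, t_max = 6) {
  stop_if_not(all(dx <= d_max + 1e-9) && all(dt <= t_max + 1e-9),
              "edge separation beyond graph thresholds")
  1 / ((1 + dx / d_max) * (1 + dt / t_max))
}

#' Build the spatiotemporal graph of a monitoring network
#'
#' One node per (station, hour); an edge connects two nodes iff their
#' stations are within `d_max` km (great-circle) and their hours within
#' `t_max` hours, both inclusive. Edge weights come from the distance-decay
#' `kernel`; every node carries a self-loop of weight `kernel(0, 0)`, which
#' keeps all degrees positive. Node `k` for station index s and hour index t
#' is `k = (s - 1) * n_hours + t` (station-major, matching the feature
#' table's row order).
#'
#' @param stations A [station_table()].
#' @param timestamps Hourly `POSIXct` grid (only its length matters; spacing
#'   is validated).
#' @param d_max Spatial threshold, km (default 50: the distance at which
#'   the areas of influence of two stations still overlap).
#' @param t_max Temporal threshold, hours (default 6: ozone varies on
#'   hourly scales).
#' @param kernel Function `(dx, dt, d_max, t_max) -> weight`, default
#'   [edge_weight()].
#' @return An `st_graph`: list with the symmetric sparse adjacency matrix
#'   `A` (`Matrix::dgCMatrix`), `degrees`, node bookkeeping, and thresholds.
#' @export
build_graph <- function(stations, timestamps, d_max = 50, t_max = 6,
                        kernel = edge_weight) {
  n_s <- nrow(stations); n_t <- length(timestamps)
  n <- n_s * n_t
  # station pairs within d_max (unordered, including i == i for self/temporal)
  D <- outer(seq_len(n_s), seq_len(n_s), function(i, j)
    station_distance(stations$latitude[i], stations$longitude[i],
                     stations$latitude[j], stations$longitude[j]))
  pair <- which(D <= d_max & upper.tri(D, diag = TRUE), arr.ind = TRUE)
  acc_i <- list(); acc_j <- list(); acc_w <- list(); nacc <- 0L
  push <- function(i, j, w) {
    nacc <<- nacc + 1L
    acc_i[[nacc]] <<- i; acc_j[[nacc]] <<- j; acc_w[[nacc]] <<- w
  }
  t_max <- as.integer(t_max)
  for (p in seq_len(nrow(pair))) {
    a <- pair[p, 1]; b <- pair[p, 2]
    dx <- D[a, b]
    for (dt in 0:t_max) {
      if (a == b && dt == 0L) {          # self-loop
        k <- (a - 1L) * n_t + seq_len(n_t)
        push(k, k, rep(kernel(0, 0, d_max, t_max), n_t))
        next
      }
      if (dt >= n_t) break
      w <- kernel(dx, dt, d_max, t_max)
      tA <- seq_len(n_t - dt); tB <- tA + dt
      kA <- (a - 1L) * n_t + tA; kB <- (b - 1L) * n_t + tB
      push(c(kA, kB), c(kB, kA), rep(w, 2L * length(tA)))
      if (a != b && dt > 0L) {           # also the (a later, b earlier) band
        kA2 <- (a - 1L) * n_t + tB; kB2 <- (b - 1L) * n_t + tA
        push(c(kA2, kB2), c(kB2, kA2), rep(w, 2L * length(tA)))
      }
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(acc_i), j = unlist(acc_j),
                            x = unlist(acc_w), dims = c(n, n))
  structure(list(A = A, degrees = Matrix::rowSums(A), n_stations = n_s,
                 n_hours = n_t, d_max = d_max, t_max = t_max,
                 station_ids = stations$station_id),
            class = "st_graph")
}

#' @export
print.st_graph <- function(x, ...) {
  nn <- length(x$degrees)
  ne <- length(x$A@x)
  cat(sprintf(
    "st_graph: %d nodes (%d stations x %d hours), %d directed edge entries\n",
    nn, x$n_stations, x$n_hours, ne))
  cat(sprintf("  thresholds: %g km / %d h; mean weighted degree %.3f\n",
              x$d_max, x$t_max, mean(x$degrees)))
  invisible(x)
}

#' Graph summary statistics
#'
#' @param graph An `st_graph`.
#' @return List with node count, undirected edge count (self-loops counted
#'   once), mean neighbor count, and a degree summary.
#' @export
graph_stats <- function(graph) {
  nn <- length(graph$degrees)
  nz <- length(graph$A@x)
  n_self <- nn  # one self-loop per node
  n_undirected <- (nz - n_self) / 2 + n_self
  list(nodes = nn, edges = n_undirected,
       mean_neighbors = (nz - n_self) / nn,
       degree_summary = summary(graph$degrees))
}

#' Normalized adjacency operator
#'
#' Returns `S = D^{-1/2} A D^{-1/2}` as a symmetric sparse matrix; applying
#' it to a node vector costs time linear in the edge count and its spectral
#' radius is at most 1, which makes iterative propagation stable.
#'
#' @param graph An `st_graph` (or a list with `A` and `degrees`).
#' @return A sparse symmetric matrix.
#' @export
normalized_adjacency <- function(graph) {
  d <- graph$degrees
  stop_if_not(all(d > 0), "zero-degree node: graph must include self-loops")
  dinv <- 1 / sqrt(d)
  Matrix::Diagonal(x = dinv) %*% graph$A %*% Matrix::Diagonal(x = dinv)
}
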