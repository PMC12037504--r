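.asAdj <- function(g) {
  if (is(g, "BinaryGraph")) return(adjacency(g))
  A <- as.matrix(g)
  storage.mode(A) <- "integer"
  A
}

.lpModeCode <- function(lpMode) {
  match(match.arg(lpMode, c("exclude", "largest-component")),
        c("exclude", "largest-component")) - 1L
}

#' Graph metrics of a binary network
#'
#' Segregation and integration metrics of an undirected, unweighted
#' graph:
#' * `cp` — mean clustering coefficient, `mean_i 2 T_i / (k_i (k_i-1))`
#'   with `T_i` the triangles through node i; nodes of degree < 2
#'   contribute 0, keeping the denominator fixed at N across subjects.
#' * `lp` — characteristic path length, the mean breadth-first
#'   shortest-path length over connected node pairs. Binarized graphs at
#'   low sparsity can fragment; by default (`lpMode = "exclude"`)
#'   disconnected pairs are excluded from the mean and the component
#'   count is recorded; `"largest-component"` restricts to the giant
#'   component.
#' * `eloc` — local efficiency (Latora-Marchiori): mean over nodes of
#'   the global efficiency of the subgraph induced by each node's
#'   neighbors (degree < 2 contributes 0).
#' * `eglob` — global efficiency: mean over all pairs of `1/d(i,j)`,
#'   with `1/Inf = 0` for disconnected pairs.
#'
#' @param g a [BinaryGraph-class] or 0/1 adjacency matrix.
#' @param lpMode `"exclude"` (default) or `"largest-component"`.
#' @return list with `cp`, `lp`, `eloc`, `eglob`, `n_components`.
#' @export
graphMetrics <- function(g, lpMode = c("exclude", "largest-component")) {
  A <- .asAdj(g)
  m <- cpp_graph_metrics(A, .lpModeCode(lpMode))
  if (is.na(m$lp) && sum(A) == 0)
    m$lp <- NA_real_  # edgeless: lp undefined, callers decide
  m
}

#' @rdname graphMetrics
#' @export
clusteringCoefficient <- function(g) {
  A <- .asAdj(g)
  if (nrow(A) < 3) stop("clustering coefficient needs at least 3 nodes")
  cpp_graph_metrics(A, 0L)$cp
}

#' @rdname graphMetrics
#' @export
characteristicPathLength <- function(g,
    lpMode = c("exclude", "largest-component")) {
  A <- .asAdj(g)
  if (sum(A) == 0)
    stop("undefined metric: characteristic path length of an edgeless graph")
  cpp_graph_metrics(A, .lpModeCode(lpMode))$lp
}

#' @rdname graphMetrics
#' @export
globalEfficiency <- function(g) {
  A <- .asAdj(g)
  if (nrow(A) < 2) stop("global efficiency needs at least 2 nodes")
  cpp_graph_metrics(A, 0L)$eglob
}

#' @rdname graphMetrics
#' @export
localEfficiency <- function(g) {
  A <- .asAdj(g)
  if (nrow(A) < 2) stop("local efficiency needs at least 2 nodes")
  cpp_graph_metrics(A, 0L)$eloc
}

#' Breadth-first shortest-path distances
#'
#' @param g a [BinaryGraph-class] or adjacency matrix.
#' @return integer N x N matrix of geodesic distances, `Inf` for
#'   unreachable pairs.
#' @export
graphDistances <- function(g) {
  D <- cpp_distances(.asAdj(g))
  D[D < 0] <- Inf
  D
}
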