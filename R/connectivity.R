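#' Pearson correlation matrix from an ROI time-series matrix
#'
#' Computes the N x N matrix of Pearson correlations between all column
#' pairs. Constant (zero-variance) columns yield zero correlations for
#' that node, with a warning; the diagonal is exactly 1.
#'
#' @param ts numeric T x N matrix, T >= 3.
#' @return symmetric N x N correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3)
    stop("insufficient data: need at least 3 timepoints, got ", nrow(ts))
  sds <- apply(ts, 2, sd)
  cm <- suppressWarnings(cor(ts))
  if (any(sds == 0)) {
    warning("constant column(s) ", paste(which(sds == 0), collapse = ", "),
            "; correlations for these nodes set to 0")
    cm[sds == 0, ] <- 0
    cm[, sds == 0] <- 0
  }
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  cm <- (cm + t(cm)) / 2
  cm
}

# edge enumeration in lexicographic (i, j) node order, i < j
.edgePairs <- function(n) {
  ij <- t(combn(n, 2L))
  colnames(ij) <- c("i", "j")
  ij
}

# half-away-from-zero rounding at the edge-count boundary
.roundHalfUp <- function(x) floor(x + 0.5)

# descending edge ranking shared by thresholdBySparsity / sparsitySweep;
# ties broken by lexicographic (i, j) order for reproducibility
.edgeOrder <- function(corr, ranking) {
  ij <- .edgePairs(nrow(corr))
  v <- corr[ij]
  key <- if (ranking == "absolute") -abs(v) else -v
  list(ij = ij, ord = order(key, ij[, 1], ij[, 2]))
}

.graphFromTopEdges <- function(corr, ij, ord, k, s) {
  n <- nrow(corr)
  A <- matrix(0L, n, n, dimnames = dimnames(corr))
  sel <- ij[ord[seq_len(k)], , drop = FALSE]
  A[sel] <- 1L
  A[sel[, 2:1, drop = FALSE]] <- 1L
  new("BinaryGraph", adjacency = A, sparsity = s, edgeCount = as.integer(k))
}

#' Binarize a correlation matrix at a target sparsity
#'
#' Retains exactly `round(s * N(N-1)/2)` edges (half-away-from-zero
#' rounding) with the largest correlations and sets them to 1. By
#' default edges are ranked by signed correlation descending (strongest
#' positive first, the usual convention for binarized functional
#' networks); `ranking = "absolute"` ranks by |r|. Ties are broken by
#' lexicographic (i, j) node order, which also makes edge sets nested
#' across increasing sparsity.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param s sparsity in (0, 1); must retain at least one edge.
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return a [BinaryGraph-class].
#' @export
thresholdBySparsity <- function(corr, s, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (s <= 0 || s >= 1) stop("sparsity must lie in (0, 1), got ", s)
  n <- nrow(corr)
  m <- n * (n - 1) / 2
  k <- .roundHalfUp(s * m)
  if (k < 1)
    stop(sprintf("degenerate sparsity: s = %g retains 0 of %d edges", s, m))
  eo <- .edgeOrder(corr, ranking)
  .graphFromTopEdges(corr, eo$ij, eo$ord, k, s)
}

#' Sparsity grid
#'
#' Ordered sparsity levels `sMin, sMin + step, ...` up to `sMax`. The
#' default grid 0.08-0.48 in steps of 0.01 (41 levels) spans the density
#' range over which group results are reported; the wider methods-style
#' 8-50% range is available by setting `sMax = 0.50`.
#'
#' @param sMin,sMax,step fractions.
#' @return numeric vector of strictly increasing levels.
#' @export
sparsityGrid <- function(sMin = 0.08, sMax = 0.48, step = 0.01) {
  if (step <= 0) stop("step must be positive")
  if (sMax < sMin) stop("sMax must be >= sMin")
  k <- floor((sMax - sMin) / step + 1e-9)
  round(sMin + step * (0:k), 10)
}

#' Binarize across a sparsity sweep
#'
#' One [BinaryGraph-class] per grid level. Because the edge ranking is
#' computed once, edge sets are nested: the graph at each level contains
#' every edge of all lower levels, and subjects thresholded at the same
#' level have identical edge counts regardless of their correlation
#' distributions.
#'
#' @inheritParams thresholdBySparsity
#' @param grid numeric vector of sparsity levels (see [sparsityGrid()]).
#' @return named list of [BinaryGraph-class], names = sparsity levels.
#' @export
sparsitySweep <- function(corr, grid = sparsityGrid(),
                          ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid levels must be strictly increasing")
  n <- nrow(corr)
  m <- n * (n - 1) / 2
  eo <- .edgeOrder(corr, ranking)
  out <- lapply(grid, function(s) {
    if (s <= 0 || s >= 1) stop("sparsity must lie in (0, 1), got ", s)
    k <- .roundHalfUp(s * m)
    if (k < 1)
      stop(sprintf("degenerate sparsity: s = %g retains 0 of %d edges",
                   s, m))
    .graphFromTopEdges(corr, eo$ij, eo$ord, k, s)
  })
  names(out) <- format(grid)
  out
}

#' Write a correlation matrix / read it back
#'
#' @param corr matrix; @param path TSV path.
#' @return `path` invisibly, or the matrix for the reader.
#' @export
writeCorrMatrix <- function(corr, path) {
  write.table(format(corr, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrMatrix
#' @export
readCorrMatrix <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write a binary graph as an edge list
#'
#' Tab-separated `i j` pairs, 1-based node indices, i < j.
#' @param g a [BinaryGraph-class]; @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  stopifnot(is(g, "BinaryGraph"))
  A <- adjacency(g)
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  write.table(idx, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
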