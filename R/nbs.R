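#' Fisher z-transform of correlations
#'
#' `atanh` with clipping just inside +/-1 so unit correlations stay
#' finite; standard variance stabilization before edgewise tests.
#'
#' @param r correlations.
#' @return z values.
#' @export
fisherZ <- function(r) atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))

# stack the upper triangle of each matrix into a subjects x edges matrix
.edgeData <- function(matrices, transform = c("fisher", "none")) {
  transform <- match.arg(transform)
  n <- nrow(matrices[[1]])
  ij <- .edgePairs(n)
  X <- t(vapply(matrices, function(m) m[ij], numeric(nrow(ij))))
  if (transform == "fisher") X <- fisherZ(X)
  list(X = X, ij = ij, n = n)
}

# vectorized pooled-variance two-sample t over edge columns
.tTwoSample <- function(X, idxA, idxB) {
  na <- length(idxA); nb <- length(idxB)
  ma <- colMeans(X[idxA, , drop = FALSE])
  mb <- colMeans(X[idxB, , drop = FALSE])
  va <- colSums(X[idxA, , drop = FALSE]^2) - na * ma^2
  vb <- colSums(X[idxB, , drop = FALSE]^2) - nb * mb^2
  sp <- sqrt((va + vb) / (na + nb - 2) * (1 / na + 1 / nb))
  t <- (ma - mb) / sp
  t[!is.finite(t)] <- 0
  t
}

# vectorized one-sample t over edge columns of a difference matrix
.tOneSample <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[!is.finite(t)] <- 0
  t
}

#' Edgewise test statistics between two sets of connectivity matrices
#'
#' Per-edge t statistics on Fisher z-transformed correlations:
#' pooled-variance two-sample t for an unpaired design, one-sample t on
#' within-pair differences (`a - b`) for a paired design. Set
#' `transform = "none"` when the inputs are already change/z matrices.
#'
#' @param matricesA,matricesB lists of N x N symmetric matrices; paired
#'   designs require equal, subject-aligned lists.
#' @param design `"unpaired"` or `"paired"`.
#' @param transform `"fisher"` (default) or `"none"`.
#' @return symmetric N x N matrix of t values (zero diagonal) with
#'   attributes `df` and `design`.
#' @export
edgewiseStats <- function(matricesA, matricesB,
                          design = c("unpaired", "paired"),
                          transform = c("fisher", "none")) {
  design <- match.arg(design)
  if (length(matricesA) < 2 || length(matricesB) < 2)
    stop("need at least 2 subjects per group")
  if (design == "paired" && length(matricesA) != length(matricesB))
    stop("pairing error: paired design requires equal, aligned lists")
  ed <- .edgeData(c(matricesA, matricesB), transform)
  na <- length(matricesA)
  if (design == "unpaired") {
    t <- .tTwoSample(ed$X, seq_len(na), na + seq_along(matricesB))
    df <- na + length(matricesB) - 2
  } else {
    D <- ed$X[seq_len(na), , drop = FALSE] -
      ed$X[na + seq_len(na), , drop = FALSE]
    t <- .tOneSample(D)
    df <- na - 1
  }
  out <- matrix(0, ed$n, ed$n, dimnames = dimnames(matricesA[[1]]))
  out[ed$ij] <- t
  out[ed$ij[, 2:1, drop = FALSE]] <- t
  attr(out, "df") <- df
  attr(out, "design") <- design
  out
}

#' Connected components of supra-threshold edges
#'
#' Edges with `t > tThr` (direction `"greater"`) or `t < -tThr`
#' (`"less"`) form a graph; its connected components (by shared
#' endpoints) are returned with size measured in edges.
#'
#' @param tMatrix symmetric edge-statistic matrix.
#' @param tThr positive primary threshold.
#' @param direction `"greater"` or `"less"`.
#' @return list of components, each a list with `edges` (k x 2 matrix,
#'   1-based, i < j), `size` (edge count) and `mass` (sum of |t|);
#'   sorted by descending size. Empty list when nothing is
#'   supra-threshold.
#' @export
supraThresholdComponents <- function(tMatrix, tThr,
                                     direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (tThr <= 0) stop("primary threshold must be positive")
  n <- nrow(tMatrix)
  ij <- .edgePairs(n)
  tv <- tMatrix[ij]
  keep <- if (direction == "greater") tv > tThr else tv < -tThr
  if (!any(keep)) return(list())
  ij <- ij[keep, , drop = FALSE]
  tv <- tv[keep]
  lab <- cpp_components(ij[, 1], ij[, 2], n)
  edgeLab <- lab[ij[, 1]]
  comps <- lapply(unique(edgeLab), function(l) {
    sel <- edgeLab == l
    list(edges = ij[sel, , drop = FALSE], size = sum(sel),
         mass = sum(abs(tv[sel])))
  })
  comps[order(-vapply(comps, `[[`, numeric(1), "size"))]
}

# max component statistic (extent or intensity) of a t-vector over edges
.maxComponentStat <- function(tv, ij, n, tThr, direction, statistic) {
  keep <- if (direction == "greater") tv > tThr else tv < -tThr
  if (!any(keep)) return(0)
  sub <- ij[keep, , drop = FALSE]
  lab <- cpp_components(sub[, 1], sub[, 2], n)
  edgeLab <- lab[sub[, 1]]
  if (statistic == "extent") max(tabulate(edgeLab))
  else max(tapply(abs(tv[keep]), edgeLab, sum))
}

#' Network-based statistic (NBS) permutation inference
#'
#' Identifies connected components of edges whose statistics exceed a
#' primary threshold and assigns each a family-wise-error-corrected
#' p-value by comparing its statistic (extent = edge count, the original
#' NBS statistic, or intensity = supra-threshold t-mass) against the
#' permutation distribution of the maximum component statistic.
#' Permutation: group-label exchange (unpaired) or per-pair sign flips
#' of the difference matrices (paired). p-values use the add-one rule
#' `(1 + #\{max >= observed\}) / (1 + nPerm)` and are never exactly 0.
#'
#' The primary threshold defaults to the t-value at `pThr = 0.01`
#' (two-sided) for the design's degrees of freedom — the most common NBS
#' choice; results should be read as conditional on it.
#'
#' @inheritParams edgewiseStats
#' @param tThr explicit primary threshold on |t|; overrides `pThr`.
#' @param pThr primary threshold as a two-sided p-value, default 0.01.
#' @param nPerm number of permutations, default 5000 (>= 100).
#' @param rngSeed integer seed for the permutation stream.
#' @param direction `"greater"` (a > b) or `"less"`.
#' @param statistic `"extent"` (default) or `"intensity"`. The extent
#'   statistic is insensitive to focal single-edge effects (an isolated
#'   supra-threshold edge has extent 1, which permutations match almost
#'   surely); use `"intensity"` when focal effects are of interest.
#' @param alpha component-level significance level recorded in the
#'   result.
#' @return an [NBSResult-class].
#' @export
nbsPermutation <- function(matricesA, matricesB,
                           design = c("unpaired", "paired"),
                           tThr = NULL, pThr = 0.01, nPerm = 5000,
                           rngSeed = NULL,
                           direction = c("greater", "less"),
                           statistic = c("extent", "intensity"),
                           transform = c("fisher", "none"),
                           alpha = 0.05) {
  design <- match.arg(design)
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  if (nPerm < 100) stop("nPerm must be >= 100")
  na <- length(matricesA); nb <- length(matricesB)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  if (design == "paired" && na != nb)
    stop("pairing error: paired design requires equal, aligned lists")
  ed <- .edgeData(c(matricesA, matricesB), match.arg(transform))
  if (design == "paired") {
    D <- ed$X[seq_len(na), , drop = FALSE] -
      ed$X[na + seq_len(na), , drop = FALSE]
    if (all(apply(D, 2, sd) == 0))
      stop("degenerate variance: all paired differences are constant")
    df <- na - 1
    tObs <- .tOneSample(D)
  } else {
    df <- na + nb - 2
    tObs <- .tTwoSample(ed$X, seq_len(na), na + seq_len(nb))
  }
  if (is.null(tThr)) tThr <- qt(1 - pThr / 2, df)
  tMat <- matrix(0, ed$n, ed$n, dimnames = dimnames(matricesA[[1]]))
  tMat[ed$ij] <- tObs
  tMat[ed$ij[, 2:1, drop = FALSE]] <- tObs
  comps <- supraThresholdComponents(tMat, tThr, direction)

  if (!is.null(rngSeed)) set.seed(rngSeed)
  nullMax <- numeric(nPerm)
  if (design == "paired") {
    for (p in seq_len(nPerm)) {
      flips <- sample(c(-1, 1), na, replace = TRUE)
      tv <- .tOneSample(D * flips)
      nullMax[p] <- .maxComponentStat(tv, ed$ij, ed$n, tThr, direction,
                                      statistic)
    }
  } else {
    for (p in seq_len(nPerm)) {
      idxA <- sample.int(na + nb, na)
      tv <- .tTwoSample(ed$X, idxA, setdiff(seq_len(na + nb), idxA))
      nullMax[p] <- .maxComponentStat(tv, ed$ij, ed$n, tThr, direction,
                                      statistic)
    }
  }
  comps <- lapply(comps, function(cmp) {
    cmp$stat <- if (statistic == "extent") cmp$size else cmp$mass
    cmp$p_perm <- (1 + sum(nullMax >= cmp$stat)) / (1 + nPerm)
    cmp
  })
  comps <- comps[order(-vapply(comps, `[[`, numeric(1), "stat"))]
  new("NBSResult", components = comps, thresholdT = tThr,
      nPerm = as.integer(nPerm), alpha = alpha, design = design,
      direction = direction, statistic = statistic, nullMax = nullMax)
}

#' Tabulate an NBS result as one row per component edge
#'
#' @param x an [NBSResult-class].
#' @param tMatrix optional edge-statistic matrix to report per-edge t.
#' @param nodeTable optional [NodeTable-class] for abbreviation labels.
#' @return data.frame `node_i, node_j, node_i_abbrev, node_j_abbrev, t,
#'   component_id, component_size, p_perm` (empty when no components).
#' @export
nbsReport <- function(x, tMatrix = NULL, nodeTable = NULL) {
  stopifnot(is(x, "NBSResult"))
  if (!length(x@components))
    return(data.frame(node_i = integer(0), node_j = integer(0),
                      node_i_abbrev = character(0),
                      node_j_abbrev = character(0), t = numeric(0),
                      component_id = integer(0),
                      component_size = integer(0), p_perm = numeric(0)))
  ab <- if (is.null(nodeTable)) NULL else abbreviations(nodeTable)
  rows <- lapply(seq_along(x@components), function(k) {
    cmp <- x@components[[k]]
    data.frame(
      node_i = cmp$edges[, 1], node_j = cmp$edges[, 2],
      node_i_abbrev = if (is.null(ab)) as.character(cmp$edges[, 1])
                      else ab[cmp$edges[, 1]],
      node_j_abbrev = if (is.null(ab)) as.character(cmp$edges[, 2])
                      else ab[cmp$edges[, 2]],
      t = if (is.null(tMatrix)) NA_real_ else tMatrix[cmp$edges],
      component_id = k, component_size = cmp$size, p_perm = cmp$p_perm,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
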