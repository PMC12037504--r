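#' Degree-preserving random rewiring (Maslov-Sneppen)
#'
#' Randomizes a binary graph by repeated double-edge swaps
#' `(a,b),(c,d) -> (a,d),(b,c)`, each accepted only if it creates no
#' self-loop or multi-edge, so the degree sequence is preserved exactly.
#' `swapFactor * edgeCount` successful swaps are attempted (ten per edge
#' is the standard mixing heuristic). Graphs admitting no legal swap
#' (e.g. complete graphs) are returned unchanged with a warning.
#'
#' @param g a [BinaryGraph-class] or 0/1 adjacency matrix.
#' @param swapFactor successful swaps per edge, default 10.
#' @param rngSeed optional integer seed (uses R's RNG; omit to draw from
#'   the current RNG state).
#' @param maxTryFactor attempts allowed per requested swap before giving
#'   up (guards against graphs with few legal swaps).
#' @return a [BinaryGraph-class] (or matrix, matching the input type)
#'   with attribute `swaps` = successful swap count.
#' @export
rewirePreservingDegree <- function(g, swapFactor = 10, rngSeed = NULL,
                                   maxTryFactor = 100L) {
  A <- .asAdj(g)
  if (sum(A) < 4) stop("rewiring needs at least 2 edges")
  if (!is.null(rngSeed)) set.seed(rngSeed)
  res <- cpp_rewire(A, swapFactor, as.integer(maxTryFactor))
  if (res$swaps < res$target)
    warning(sprintf(
      "only %d of %d requested swaps were possible; graph returned %s",
      res$swaps, res$target,
      if (res$swaps == 0) "unchanged" else "partially rewired"))
  out <- res$adj
  dimnames(out) <- dimnames(A)
  if (is(g, "BinaryGraph")) {
    bg <- new("BinaryGraph", adjacency = out, sparsity = sparsity(g),
              edgeCount = edgeCount(g))
    attr(bg, "swaps") <- res$swaps
    return(bg)
  }
  attr(out, "swaps") <- res$swaps
  out
}

#' Small-world metrics normalized by degree-preserving nulls
#'
#' gamma = cp / mean null cp, lambda = lp / mean null lp, and
#' small-worldness sigma = gamma / lambda. Nulls are Maslov-Sneppen
#' rewirings of the input (not forced to be connected); their `lp` uses
#' the same disconnection rule as the empirical graph, so the
#' normalization is symmetric.
#'
#' @inheritParams rewirePreservingDegree
#' @param nNull number of null graphs (>= 1), default 100.
#' @param lpMode disconnection rule, see [graphMetrics()].
#' @return list with `gamma`, `lambda`, `sigma`, `cp`, `lp`, `n_null`,
#'   `null_cp_mean`, `null_lp_mean`.
#' @export
normalizedSmallWorld <- function(g, nNull = 100, swapFactor = 10,
                                 rngSeed = NULL,
                                 lpMode = c("exclude", "largest-component"),
                                 maxTryFactor = 100L) {
  A <- .asAdj(g)
  if (sum(A) == 0) stop("small-world metrics need at least one edge")
  if (nNull < 1) stop("nNull must be >= 1")
  lpc <- .lpModeCode(lpMode)
  obs <- cpp_graph_metrics(A, lpc)
  if (!is.null(rngSeed)) set.seed(rngSeed)
  nulls <- cpp_null_cp_lp(A, as.integer(nNull), swapFactor, lpc,
                          as.integer(maxTryFactor))
  nullCp <- mean(nulls[, 1])
  nullLp <- mean(nulls[, 2], na.rm = TRUE)
  if (!is.finite(nullCp) || nullCp <= 0 || !is.finite(nullLp) || nullLp <= 0)
    stop("degenerate null: mean null cp or lp is zero")
  gamma <- obs$cp / nullCp
  lambda <- obs$lp / nullLp
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp = obs$cp, lp = obs$lp, n_null = as.integer(nNull),
       null_cp_mean = nullCp, null_lp_mean = nullLp)
}

#' Metric curves across the sparsity sweep for one subject
#'
#' Thresholds a correlation matrix at every grid level and computes the
#' raw metrics (cp, lp, eloc, eglob) plus the null-normalized gamma,
#' lambda and sigma at each level.
#'
#' @inheritParams sparsitySweep
#' @inheritParams normalizedSmallWorld
#' @return data.frame with one row per sparsity level and columns
#'   `sparsity, cp, lp, eloc, eglob, gamma, lambda, sigma,
#'   n_components`.
#' @export
smallWorldSweep <- function(corr, grid = sparsityGrid(), nNull = 100,
                            swapFactor = 10, rngSeed = NULL,
                            lpMode = c("exclude", "largest-component"),
                            ranking = c("signed", "absolute")) {
  lpMode <- match.arg(lpMode)
  graphs <- sparsitySweep(corr, grid, match.arg(ranking))
  if (!is.null(rngSeed)) set.seed(rngSeed)
  rows <- lapply(seq_along(grid), function(k) {
    g <- graphs[[k]]
    m <- graphMetrics(g, lpMode)
    sw <- normalizedSmallWorld(g, nNull = nNull, swapFactor = swapFactor,
                               lpMode = lpMode)
    data.frame(sparsity = grid[k], cp = m$cp, lp = m$lp, eloc = m$eloc,
               eglob = m$eglob, gamma = sw$gamma, lambda = sw$lambda,
               sigma = sw$sigma, n_components = m$n_components)
  })
  do.call(rbind, rows)
}

#' Area under a metric curve across the sparsity grid
#'
#' Trapezoidal integral of a metric over its sparsity grid; a constant
#' curve `c` over `[a, b]` integrates to `c * (b - a)`.
#'
#' @param sparsities strictly increasing grid (>= 2 points).
#' @param values metric values, same length.
#' @return scalar AUC (metric units x sparsity).
#' @export
metricAUC <- function(sparsities, values) {
  if (length(sparsities) < 2)
    stop("insufficient grid: AUC needs at least 2 points")
  if (length(values) != length(sparsities))
    stop("sparsities and values must have equal length")
  if (is.unsorted(sparsities, strictly = TRUE))
    stop("sparsities must be strictly increasing")
  pracma::trapz(sparsities, values)
}

#' AUC of every metric in a sweep data.frame
#'
#' @param sweep data.frame from [smallWorldSweep()].
#' @return named numeric vector of AUCs for
#'   `cp, lp, eloc, eglob, gamma, lambda, sigma`.
#' @export
aucTable <- function(sweep) {
  metrics <- c("cp", "lp", "eloc", "eglob", "gamma", "lambda", "sigma")
  vapply(metrics,
         function(mname) metricAUC(sweep$sparsity, sweep[[mname]]),
         numeric(1))
}

#' Per-subject metric curves and AUCs for a whole cohort
#'
#' Runs [smallWorldSweep()] on every record and returns long-format
#' curves plus a wide AUC table with the clinical covariates attached.
#'
#' @param cohort a [Cohort-class]; records need time series or
#'   correlation matrices.
#' @inheritParams smallWorldSweep
#' @return list with `curves` (long data.frame: `subject_id, session,
#'   group, sparsity, metric, value`) and `auc` (one row per record:
#'   ids, covariates and the 7 metric AUC columns).
#' @export
cohortMetrics <- function(cohort, grid = sparsityGrid(), nNull = 100,
                          swapFactor = 10, rngSeed = NULL,
                          lpMode = c("exclude", "largest-component"),
                          ranking = c("signed", "absolute")) {
  lpMode <- match.arg(lpMode)
  ranking <- match.arg(ranking)
  if (!is.null(rngSeed)) set.seed(rngSeed)
  curveRows <- list()
  aucRows <- list()
  for (r in records(cohort)) {
    cm <- subjectCorr(r)
    sw <- smallWorldSweep(cm, grid, nNull = nNull, swapFactor = swapFactor,
                          lpMode = lpMode, ranking = ranking)
    long <- do.call(rbind, lapply(
      c("cp", "lp", "eloc", "eglob", "gamma", "lambda", "sigma"),
      function(mname) data.frame(
        subject_id = r@subjectId, session = r@session, group = r@group,
        sparsity = sw$sparsity, metric = mname, value = sw[[mname]],
        stringsAsFactors = FALSE)))
    curveRows[[length(curveRows) + 1]] <- long
    a <- aucTable(sw)
    aucRows[[length(aucRows) + 1]] <- data.frame(
      subject_id = r@subjectId, session = r@session, group = r@group,
      age = r@age, sex = r@sex, fd = r@fd, ahrs = r@ahrs,
      t(a), stringsAsFactors = FALSE)
  }
  list(curves = do.call(rbind, curveRows), auc = do.call(rbind, aucRows))
}

#' Correlation matrix of a subject record
#'
#' Returns the stored correlation matrix, or computes it from the time
#' series when only the series is present.
#' @param record a [SubjectRecord-class].
#' @return N x N correlation matrix.
#' @export
subjectCorr <- function(record) {
  if (!is.null(record@corr)) return(record@corr)
  correlationMatrix(record@timeseries)
}
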