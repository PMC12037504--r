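# Independent oracles used to cross-check the package's own
# implementations. These deliberately take different routes: igraph for
# graph metrics, plain-R brute force for BH step-up, trapezoid sums,
# t formulas, union-find and normal equations.

# reference graph metrics via igraph (exclude-disconnected lp rule)
oracleMetrics <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  n <- nrow(A)
  D <- igraph::distances(g)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  fin <- is.finite(D) & D > 0
  eglobSub <- function(M) {
    k <- nrow(M)
    if (k < 2) return(0)
    gs <- igraph::graph_from_adjacency_matrix(M, mode = "undirected")
    Ds <- igraph::distances(gs)
    f <- is.finite(Ds) & Ds > 0
    sum(1 / Ds[f]) / (k * (k - 1))
  }
  eloc <- mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    eglobSub(A[nb, nb, drop = FALSE])
  }, numeric(1)))
  list(cp = mean(loc),
       lp = if (any(fin)) mean(D[fin]) else NA_real_,
       eloc = eloc,
       eglob = sum(1 / D[fin]) / (n * (n - 1)))
}

# brute-force triangle count for one node's clustering (triple loop)
oracleClustering <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (A[nb[a], nb[b]] == 1) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1)))
}

# Erdos-Renyi-style random 0/1 adjacency with fixed edge probability
randomAdj <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(runif(length(up)) < p)
  A + t(A)
}

# BH step-up from first principles
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  val <- p[o] * m / seq_len(m)
  val <- rev(cummin(rev(val)))
  out <- numeric(m)
  out[o] <- pmin(val, 1)
  out
}

# trapezoid quadrature by explicit summation
oracleTrapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i + 1] + y[i]) / 2
  s
}

# textbook pooled-variance two-sample t
oracleTwoSampleT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# least-squares residuals via explicit normal equations
oracleResiduals <- function(y, X) {
  beta <- solve(t(X) %*% X) %*% t(X) %*% y
  as.numeric(y - X %*% beta)
}

# connected components of an edge list by naive label propagation
oracleComponents <- function(edges, n) {
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      m <- min(lab[i], lab[j])
      if (lab[i] != m || lab[j] != m) {
        lab[lab == lab[i] | lab == lab[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# random symmetric "correlation" matrix from a short random time series
randomCorr <- function(n = 35, tlen = 60) {
  correlationMatrix(matrix(rnorm(tlen * n), tlen, n))
}

# symmetric matrix of Fisher-z values turned into a correlation matrix
corrFromZ <- function(z) {
  r <- tanh((z + t(z)) / 2)
  diag(r) <- 1
  r
}

# random z-noise matrices for two groups, optional per-edge shift in b
zGroupMatrices <- function(nA, nB, n = 35, sd = 0.15, shift = NULL) {
  mk <- function(extra) {
    z <- matrix(rnorm(n * n, 0, sd), n, n)
    if (!is.null(extra)) z <- z + extra
    corrFromZ(z)
  }
  shiftM <- NULL
  if (!is.null(shift)) {
    shiftM <- matrix(0, n, n)
    for (k in seq_len(nrow(shift$edges))) {
      i <- shift$edges[k, 1]; j <- shift$edges[k, 2]
      shiftM[i, j] <- shiftM[j, i] <- shift$delta
    }
  }
  list(a = replicate(nA, mk(NULL), simplify = FALSE),
       b = replicate(nB, mk(shiftM), simplify = FALSE))
}

fixturePath <- function(f)
  system.file("extdata", f, package = "avhnet", mustWork = TRUE)
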