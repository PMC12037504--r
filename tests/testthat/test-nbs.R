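test_that("edgewise statistics vanish for identical groups", {
  set.seed(101)
  mats <- replicate(5, randomCorr(10, 40), simplify = FALSE)
  tM <- edgewiseStats(mats, mats, design = "unpaired")
  expect_equal(max(abs(tM)), 0)
  tP <- edgewiseStats(mats, mats, design = "paired")
  expect_equal(max(abs(tP)), 0)
})

test_that("edgewise t matches the textbook formula on a printed toy", {
  set.seed(103)
  a <- replicate(4, corrFromZ(matrix(rnorm(25, 0, 0.2), 5, 5)),
                 simplify = FALSE)
  b <- replicate(5, corrFromZ(matrix(rnorm(25, 0, 0.2), 5, 5)),
                 simplify = FALSE)
  tM <- edgewiseStats(a, b, design = "unpaired")
  for (i in 1:4) for (j in (i + 1):5) {
    za <- vapply(a, function(m) atanh(m[i, j]), numeric(1))
    zb <- vapply(b, function(m) atanh(m[i, j]), numeric(1))
    expect_equal(tM[i, j], oracleTwoSampleT(za, zb), tolerance = 1e-10)
  }
  expect_equal(attr(tM, "df"), 7)
  expect_error(edgewiseStats(a, b, design = "paired"), "pairing error")
})

test_that("a planted edge shift carries the maximum statistic", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    gm <- zGroupMatrices(20, 20, n = 20, sd = 0.15,
                         shift = list(edges = rbind(c(3, 11)),
                                      delta = 0.3))
    tM <- edgewiseStats(gm$a, gm$b, design = "unpaired")
    peak <- which(abs(tM) == max(abs(tM)), arr.ind = TRUE)
    if (any(peak[, 1] == 3 & peak[, 2] == 11)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("supra-threshold components form by shared endpoints", {
  n <- 6
  tM <- matrix(0, n, n)
  expect_length(supraThresholdComponents(tM, 2), 0)

  # a 3-edge path of supra-threshold edges is one component of size 3
  for (e in list(c(1, 2), c(2, 3), c(3, 4))) {
    tM[e[1], e[2]] <- tM[e[2], e[1]] <- 3
  }
  comps <- supraThresholdComponents(tM, 2)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size, 3)
  expect_equal(comps[[1]]$mass, 9)

  # direction "less" picks up negative edges only
  tM2 <- -tM
  expect_length(supraThresholdComponents(tM2, 2, "greater"), 0)
  expect_equal(supraThresholdComponents(tM2, 2, "less")[[1]]$size, 3)
  expect_error(supraThresholdComponents(tM, -1), "positive")
})

test_that("component extraction agrees with a label-propagation oracle", {
  set.seed(107)
  for (rep in 1:10) {
    tM <- matrix(0, 35, 35)
    up <- which(upper.tri(tM))
    tM[up] <- rnorm(length(up), 0, 1.3)
    tM <- tM + t(tM)
    comps <- supraThresholdComponents(tM, 2)
    sup <- which(upper.tri(tM) & tM > 2, arr.ind = TRUE)
    if (!nrow(sup)) {
      expect_length(comps, 0)
      next
    }
    lab <- oracleComponents(sup, 35)
    nodesOf <- function(cmp) sort(unique(as.vector(cmp$edges)))
    oracleGroups <- split(sup, lab[sup[, 1]])
    # same number of components and same edge-count multiset
    expect_equal(sort(vapply(comps, `[[`, numeric(1), "size")),
                 sort(vapply(unique(lab[sup[, 1]]), function(l)
                   sum(lab[sup[, 1]] == l), numeric(1))))
    # every component's node set is closed under the oracle labels
    for (cmp in comps) {
      nodes <- nodesOf(cmp)
      expect_length(unique(lab[nodes]), 1)
    }
  }
})

test_that("permutation p-values obey the add-one floor", {
  set.seed(109)
  gm <- zGroupMatrices(10, 10, n = 12, sd = 0.1,
                       shift = list(edges = rbind(c(1, 2), c(2, 3)),
                                    delta = 1.5))
  # intensity statistic: the planted component's t-mass is far beyond
  # anything a permutation can reach, so its p sits at the add-one floor
  nbs <- nbsPermutation(gm$a, gm$b, design = "unpaired", nPerm = 100,
                        rngSeed = 1, direction = "less",
                        statistic = "intensity")
  expect_gt(length(nbsComponents(nbs)), 0)
  top <- nbsComponents(nbs)[[1]]
  expect_equal(top$p_perm, 1 / 101)
  for (cmp in nbsComponents(nbs)) expect_gt(cmp$p_perm, 0)
})

test_that("permutation inference is reproducible and nPerm-stable", {
  set.seed(113)
  gm <- zGroupMatrices(12, 12, n = 15, sd = 0.2,
                       shift = list(edges = rbind(c(1, 2)), delta = 0.25))
  run <- function(nPerm, seed)
    nbsPermutation(gm$a, gm$b, design = "unpaired", nPerm = nPerm,
                   rngSeed = seed, direction = "less", pThr = 0.05)
  r1 <- run(200, 5)
  r2 <- run(200, 5)
  expect_identical(nbsComponents(r1), nbsComponents(r2))
  r3 <- run(400, 7)
  p1 <- nbsComponents(r1)[[1]]$p_perm
  p3 <- nbsComponents(r3)[[1]]$p_perm
  se <- sqrt(p1 * (1 - p1) / 200)
  expect_lt(abs(p1 - p3), 2 * se + 1 / 100)
})

test_that("paired sign flips match label exchange for symmetric data", {
  # pairs (a_i, b_i) = (+d_i/2, -d_i/2): the paired differences are
  # symmetric and the groups are exchangeable, so both permutation
  # schemes target the same null distribution
  set.seed(127)
  n <- 10
  mats <- lapply(1:n, function(i) {
    z <- matrix(rnorm(100, 0, 0.2), 10, 10)
    list(a = corrFromZ(z / 2), b = corrFromZ(-z / 2))
  })
  a <- lapply(mats, `[[`, "a")
  b <- lapply(mats, `[[`, "b")
  rp <- nbsPermutation(a, b, design = "paired", nPerm = 600, rngSeed = 3,
                       pThr = 0.05)
  ru <- nbsPermutation(a, b, design = "unpaired", nPerm = 600, rngSeed = 3,
                       pThr = 0.05)
  mp <- mean(rp@nullMax)
  mu <- mean(ru@nullMax)
  sep <- sd(rp@nullMax) / sqrt(600)
  seu <- sd(ru@nullMax) / sqrt(600)
  expect_lt(abs(mp - mu), 4 * sqrt(sep^2 + seu^2) + 0.25)
})

test_that("NBS reports tabulate component edges with labels", {
  set.seed(131)
  gm <- zGroupMatrices(8, 8, n = 35, sd = 0.1,
                       shift = list(edges = rbind(c(26, 16), c(16, 2)),
                                    delta = 1))
  nbs <- nbsPermutation(gm$a, gm$b, design = "unpaired", nPerm = 100,
                        rngSeed = 1, direction = "less")
  tM <- edgewiseStats(gm$a, gm$b, design = "unpaired")
  rep <- nbsReport(nbs, tMatrix = tM, nodeTable = avhNodeTable())
  expect_true(all(c("node_i_abbrev", "p_perm", "component_size") %in%
                    names(rep)))
  expect_true(any(rep$node_i_abbrev == "LPFC.L" |
                    rep$node_j_abbrev == "LPFC.L"))
})
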