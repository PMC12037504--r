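test_that("residualization removes exactly the covariate-explained part", {
  set.seed(61)
  age <- rnorm(30, 25, 5)
  # perfectly linear in age -> residuals vanish
  r <- residualize(3 + 0.2 * age, data.frame(age = age))
  expect_equal(max(abs(r)), 0, tolerance = 1e-10)

  # covariates orthogonal to the values -> residuals = centered values
  v <- rep(c(-1, 1), 15)
  cov <- data.frame(x = rep(c(1, 1, -1, -1), length.out = 30))
  expect_equal(residualize(v, cov), v - mean(v), tolerance = 1e-10)

  # 40-subject fixture vs explicit normal equations
  covs <- data.frame(age = rnorm(40, 25, 5),
                     sex = sample(c("male", "female"), 40, TRUE),
                     fd = rnorm(40, 0.28, 0.05))
  y <- rnorm(40)
  X <- cbind(1, covs$age, as.numeric(covs$sex == "male"), covs$fd)
  expect_equal(residualize(y, covs), oracleResiduals(y, X),
               tolerance = 1e-10)
  expect_equal(sum(residualize(y, covs)), 0, tolerance = 1e-8)

  # collinear design is rejected with the offending column named
  bad <- data.frame(age = covs$age, age2 = 2 * covs$age)
  expect_error(residualize(y, bad), "collinearity")
})

test_that("t tests match closed forms and reject degenerate variance", {
  a <- c(1, 2, 3, 4)
  r0 <- twoSampleTest(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_raw, 1)

  set.seed(67)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  r1 <- twoSampleTest(x, y, metric = "cp", contrast = "HC_vs_pre")
  expect_equal(r1$t, oracleTwoSampleT(x, y), tolerance = 1e-12)
  expect_equal(r1$df, 18)

  expect_error(twoSampleTest(rep(1, 5), rep(2, 5)), "degenerate variance")
  expect_error(pairedTest(x, x + 2), "degenerate variance")

  r2 <- pairedTest(x, y)
  d <- y - x
  expect_equal(r2$t, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrBH(rep(1, 5)), rep(1, 5))
  expect_equal(fdrBH(0.37), 0.37)
  expect_error(fdrBH(c(0.5, 1.2)), "validation")
  set.seed(71)
  for (rep in 1:200) {
    p <- runif(sample(1:30, 1))
    expect_equal(fdrBH(p), oracleBH(p), tolerance = 1e-12)
  }
})

test_that("symptom correlations recover exact and null relations", {
  x <- rnorm(20)
  r1 <- correlateWithSymptoms(x, 2 * x + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)

  set.seed(73)
  x <- rnorm(40); y <- rnorm(40)
  robs <- correlateWithSymptoms(x, y)$r
  nullR <- vapply(1:2000, function(i) cor(x, sample(y)), numeric(1))
  expect_lt(abs(robs), quantile(abs(nullR), 0.995))

  expect_error(correlateWithSymptoms(x[1:2], y[1:2]), "n >= 3")
  expect_error(correlateWithSymptoms(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("residualizing on irrelevant covariates leaves t unchanged", {
  # a covariate exactly orthogonal to both the values and the group
  # indicator must leave the two-sample t unchanged
  set.seed(79)
  a <- rnorm(20); b <- rnorm(24, 0.3)
  q <- qr.Q(qr(cbind(1, c(rep(1, 20), rep(0, 24)), c(a, b))))
  orth <- rnorm(44)
  orth <- orth - q %*% crossprod(q, orth)
  res <- residualize(c(a, b), data.frame(z = as.numeric(orth)))
  t1 <- twoSampleTest(res[1:20], res[21:44])$t
  expect_equal(t1, twoSampleTest(a, b)$t, tolerance = 1e-9)
})

test_that("null metric comparisons reject at the nominal rate", {
  set.seed(83)
  hits <- 0
  nSim <- 1000
  for (i in seq_len(nSim)) {
    a <- rnorm(20); b <- rnorm(20)
    if (twoSampleTest(a, b)$p_raw < 0.05) hits <- hits + 1
  }
  expect_gte(hits / nSim, 0.03)
  expect_lte(hits / nSim, 0.07)
})

test_that("group contrasts cover three contrasts with a BH family", {
  set.seed(89)
  n <- 12
  mk <- function(group, session, ids, shift)
    data.frame(subject_id = ids, session = session, group = group,
               age = rnorm(n, 25, 4),
               sex = sample(c("male", "female"), n, TRUE),
               fd = rnorm(n, 0.28, 0.04), ahrs = NA,
               cp = rnorm(n, 0.25 + shift, 0.02),
               lp = rnorm(n, 1.1, 0.05), eloc = rnorm(n, 0.3, 0.02),
               eglob = rnorm(n, 0.2, 0.02), gamma = rnorm(n, 1.2, 0.1),
               lambda = rnorm(n, 1.05, 0.03),
               sigma = rnorm(n, 1.15, 0.1))
  auc <- rbind(mk("HC", "baseline", sprintf("H%02d", 1:n), 0.05),
               mk("SZ", "baseline", sprintf("S%02d", 1:n), 0),
               mk("SZ", "post", sprintf("S%02d", 1:n), 0.02))
  ct <- groupContrasts(auc)
  expect_setequal(unique(ct$contrast),
                  c("HC_vs_pre", "HC_vs_post", "pre_vs_post"))
  expect_equal(nrow(ct), 21)
  expect_true(all(ct$p_fdr >= ct$p_raw - 1e-12))
  expect_equal(ct$p_fdr, oracleBH(ct$p_raw), tolerance = 1e-12)
  # the planted cp elevation in HC is found with the right sign
  row <- ct[ct$metric == "cp" & ct$contrast == "HC_vs_pre", ]
  expect_equal(row$direction, 1)
  expect_lt(row$p_fdr, 0.05)
})
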