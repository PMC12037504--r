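test_that("the population matrix reduces to its block definition", {
  mods <- rep(c("a", "b"), each = 4)
  # no block structure, no distance term -> identity
  s0 <- cohortSpec(modules = mods, coords = NULL, r_within = 0,
                   r_between = 0, r_dist = 0, n_hc = 2, n_sz = 2,
                   sz_segregation_deficit = 0, sz_integration_deficit = 0,
                   hub_nodes = 1L, delta_hyper = 0,
                   hyper_edges = rbind(c(1L, 5L)))
  expect_equal(buildPopulationCovariance(s0, "HC"), diag(8))

  # pure block model: within-module entries are exactly r_within
  s1 <- cohortSpec(modules = mods, coords = NULL, r_within = 0.3,
                   r_between = 0.1, r_dist = 0, n_hc = 2, n_sz = 2,
                   sz_segregation_deficit = 0.05,
                   sz_integration_deficit = 0, hub_nodes = 1L,
                   delta_hyper = 0, hyper_edges = rbind(c(1L, 5L)))
  Rhc <- buildPopulationCovariance(s1, "HC")
  same <- outer(mods, mods, "==") & !diag(8)
  expect_true(all(Rhc[same] == 0.3))
  expect_true(all(Rhc[!same & !diag(8)] == 0.1))

  # patient baseline: within-module entries lower by the segregation
  # deficit, entrywise
  Rsz <- buildPopulationCovariance(s1, "SZ", "baseline")
  expect_equal(Rhc[same] - Rsz[same], rep(0.05, sum(same)))
})

test_that("hub and hyper-edge modifications land on the right entries", {
  # deficits mild enough that no PSD repair perturbs the entries
  spec <- cohortSpec(r_dist = 0, sz_segregation_deficit = 0.03,
                     sz_integration_deficit = 0.05)
  Rhc <- buildPopulationCovariance(spec, "HC")
  Rsz <- buildPopulationCovariance(spec, "SZ", "baseline")
  expect_null(attr(Rsz, "psd_repaired"))
  hub <- spec$hub_nodes[1]
  other <- setdiff(seq_len(35), c(spec$hub_nodes,
                                  as.vector(spec$hyper_edges)))[1]
  expect_equal(Rhc[hub, other] - Rsz[hub, other],
               spec$sz_integration_deficit)
  for (e in seq_len(nrow(spec$hyper_edges))) {
    i <- spec$hyper_edges[e, 1]; j <- spec$hyper_edges[e, 2]
    expect_equal(Rsz[i, j], spec$r_between + spec$delta_hyper,
                 tolerance = 1e-12)
    expect_gt(Rsz[i, j], Rhc[i, j])
  }
})

test_that("generated covariances are PSD with unit diagonal", {
  set.seed(149)
  for (rep in 1:10) {
    spec <- cohortSpec(r_within = runif(1, 0, 0.35),
                       r_between = runif(1, 0, 0.15),
                       r_dist = runif(1, 0, 0.6),
                       sz_segregation_deficit = runif(1, 0, 0.1),
                       sz_integration_deficit = runif(1, 0, 0.5))
    for (grp in c("HC", "SZ")) {
      R <- buildPopulationCovariance(spec, grp)
      expect_equal(diag(R), rep(1, 35), ignore_attr = TRUE)
      expect_gte(min(eigen(R, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-8)
    }
  }
})

test_that("sample correlations converge to the population entrywise", {
  spec <- cohortSpec(n_hc = 1, n_sz = 0, t_len = 50000, noise_sd = 0,
                     rng_seed = 151)
  co <- simulateCohort(spec)
  cm <- subjectCorr(records(co)[[1]])
  pop <- buildPopulationCovariance(spec, "HC")
  expect_lt(max(abs(cm - pop)), 0.02)
})

test_that("cohorts are reproducible and respect the responder fraction", {
  spec <- cohortSpec(n_hc = 2, n_sz = 40, t_len = 5, rng_seed = 157)
  co1 <- simulateCohort(spec)
  co2 <- simulateCohort(spec)
  expect_identical(co1, co2)

  recs <- records(co1)
  ses <- vapply(recs, function(r) r@session, character(1))
  grp <- vapply(recs, function(r) r@group, character(1))
  ids <- vapply(recs, function(r) r@subjectId, character(1))
  pre <- recs[grp == "SZ" & ses == "baseline"]
  post <- recs[grp == "SZ" & ses == "post"]
  post <- post[match(vapply(pre, function(r) r@subjectId, character(1)),
                     vapply(post, function(r) r@subjectId, character(1)))]
  cl <- classifyResponders(vapply(pre, function(r) r@ahrs, numeric(1)),
                           vapply(post, function(r) r@ahrs, numeric(1)))
  expect_equal(cl$n_resp, 27)  # round(0.675 * 40)
  expect_equal(attr(co1, "truth")$responder,
               cl$labels$label == "responder")

  expect_error(simulateCohort(cohortSpec(t_len = 2)), "t_len")
  expect_error(cohortSpec(responder_fraction = 1.2), "responder_fraction")
  expect_error(cohortSpec(restoration_fraction = -0.1),
               "restoration_fraction")
})

test_that("HC records are baseline-only and dimensions match the atlas", {
  spec <- cohortSpec(n_hc = 3, n_sz = 2, t_len = 10, rng_seed = 163)
  co <- simulateCohort(spec)
  expect_equal(nodeCount(co), 35)
  for (r in records(co)) {
    expect_equal(ncol(r@timeseries), 35)
    if (r@group == "HC") expect_equal(r@session, "baseline")
  }
})

test_that("cohort files round-trip through the public loaders", {
  spec <- cohortSpec(n_hc = 2, n_sz = 2, t_len = 40, rng_seed = 167)
  co <- simulateCohort(spec)
  dir <- tempfile()
  writeCohortFiles(co, dir)
  nt <- loadNodeTable(file.path(dir, "node_table.tsv"))
  co2 <- loadCohort(nt, file.path(dir, "clinical.csv"), dir)
  expect_equal(length(records(co2)), length(records(co)))
  r1 <- records(co)[[1]]
  ids2 <- vapply(records(co2), function(r)
    paste(r@subjectId, r@session), character(1))
  r2 <- records(co2)[[match(paste(r1@subjectId, r1@session), ids2)]]
  expect_equal(unname(r2@timeseries), unname(r1@timeseries),
               tolerance = 1e-12)
  expect_equal(r2@ahrs, r1@ahrs, tolerance = 1e-10)
})

test_that("generated cohorts sit in the small-world regime", {
  # group-mean lambda must clear 1 at every level; per-subject gamma and
  # sigma must clear 1 at every level for >= 95% of subjects (per-subject
  # lambda at the densest levels is 1 + O(0.005) by construction: the
  # degree-matched null converges to the graph itself, so only the group
  # curve is informative there)
  spec <- cohortSpec(n_hc = 10, n_sz = 6, t_len = 180, rng_seed = 173)
  co <- simulateCohort(spec)
  met <- cohortMetrics(co, nNull = 10, rngSeed = 42)
  cur <- met$curves
  for (mm in c("gamma", "sigma")) {
    sub <- cur[cur$metric == mm, ]
    frac <- mean(aggregate(value ~ subject_id + session, sub,
                           min)$value > 1)
    expect_gte(frac, 0.95)
  }
  lam <- cur[cur$metric == "lambda", ]
  gm <- tapply(lam$value, lam$sparsity, mean)
  expect_true(all(gm > 1))
})

test_that("planted group differences propagate through the pipeline", {
  spec <- cohortSpec(n_hc = 12, n_sz = 10, t_len = 180, rng_seed = 179)
  co <- simulateCohort(spec)
  met <- cohortMetrics(co, nNull = 6, rngSeed = 42)
  a <- met$auc
  hc <- a[a$group == "HC", ]
  pre <- a[a$group == "SZ" & a$session == "baseline", ]
  for (mm in c("cp", "eloc", "eglob", "sigma"))
    expect_gt(mean(hc[[mm]]), mean(pre[[mm]]))
})

test_that("null recovery specs reject at close to the nominal rate", {
  # with no planted effects the detection columns are type-I errors;
  # pool them over replicates and compare against alpha
  spec <- cohortSpec(n_hc = 8, n_sz = 8, t_len = 60,
                     sz_segregation_deficit = 0,
                     sz_integration_deficit = 0, delta_hyper = 0,
                     coupling_slope = 0, restoration_fraction = 0)
  rep <- recoveryReport(spec, nReps = 12, rngSeed = 181, nNull = 4,
                        nPerm = 150, grid = sparsityGrid(0.1, 0.4, 0.05))
  det <- unlist(rep[, grep("^(hc|post|nbs)", names(rep))])
  rate <- mean(det, na.rm = TRUE)
  # 108 pooled null tests; the pooled rate should be near alpha = 0.05
  expect_lte(rate, 0.15)
})
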