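#' Default run configuration
#'
#' @param nodeTablePath,tsDir,clinicalPath,outDir input/output paths.
#' @param sMin,sMax,step sparsity grid.
#' @param ranking edge ranking mode (see [thresholdBySparsity()]).
#' @param lpMode path-length disconnection rule (see [graphMetrics()]).
#' @param nNull,swapFactor null-model settings.
#' @param nbsPThr,nbsNPerm,nbsStatistic NBS settings.
#' @param fdrAlpha significance level for FDR-corrected contrasts.
#' @param responderThreshold fractional AHRS reduction defining a
#'   responder (0.5).
#' @param rngSeed master seed; each stochastic stage consumes a seed
#'   derived deterministically from it plus the stage name.
#' @return config list (class `avhnet_config`).
#' @export
runConfig <- function(nodeTablePath = NULL, tsDir = NULL,
                      clinicalPath = NULL, outDir = NULL,
                      sMin = 0.08, sMax = 0.48, step = 0.01,
                      ranking = "signed", lpMode = "exclude",
                      nNull = 100, swapFactor = 10,
                      nbsPThr = 0.01, nbsNPerm = 5000,
                      nbsStatistic = "extent",
                      fdrAlpha = 0.05, responderThreshold = 0.5,
                      rngSeed = 1L) {
  cfg <- list(node_table = nodeTablePath, ts_dir = tsDir,
              clinical = clinicalPath, out_dir = outDir,
              s_min = sMin, s_max = sMax, step = step,
              ranking = ranking, lp_mode = lpMode,
              n_null = nNull, swap_factor = swapFactor,
              nbs_p_thr = nbsPThr, nbs_n_perm = nbsNPerm,
              nbs_statistic = nbsStatistic,
              fdr_alpha = fdrAlpha,
              responder_threshold = responderThreshold,
              rng_seed = as.integer(rngSeed))
  class(cfg) <- "avhnet_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Keys mirror [runConfig()]'s list names; missing keys take the
#' defaults.
#' @param path YAML file.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- runConfig()
  for (k in names(y)) cfg[[k]] <- y[[k]]
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg
}

#' Validate a run configuration without running it
#'
#' @param config config list from [runConfig()]/[readRunConfig()].
#' @param checkPaths also require the input paths to exist.
#' @return data.frame of violations (`field`, `problem`); zero rows =
#'   valid, with the grid size in `attr(x, "n_levels")`.
#' @export
validateConfig <- function(config, checkPaths = FALSE) {
  v <- list()
  bad <- function(field, problem)
    v[[length(v) + 1]] <<- data.frame(field = field, problem = problem,
                                      stringsAsFactors = FALSE)
  if (!is.numeric(config$step) || config$step <= 0)
    bad("step", "must be a positive fraction")
  if (config$s_min <= 0 || config$s_min >= 1)
    bad("s_min", "must lie in (0, 1)")
  if (config$s_max <= 0 || config$s_max >= 1)
    bad("s_max", "must lie in (0, 1)")
  if (is.numeric(config$step) && config$step > 0 &&
      config$s_max < config$s_min)
    bad("s_max", "must be >= s_min")
  if (config$n_null < 1) bad("n_null", "must be >= 1")
  if (config$swap_factor <= 0) bad("swap_factor", "must be positive")
  if (config$nbs_n_perm < 100) bad("nbs_n_perm", "must be >= 100")
  if (config$nbs_p_thr <= 0 || config$nbs_p_thr >= 1)
    bad("nbs_p_thr", "must lie in (0, 1)")
  if (config$fdr_alpha <= 0 || config$fdr_alpha >= 1)
    bad("fdr_alpha", "must lie in (0, 1)")
  if (config$responder_threshold <= 0 || config$responder_threshold >= 1)
    bad("responder_threshold", "must lie in (0, 1)")
  if (!config$ranking %in% c("signed", "absolute"))
    bad("ranking", "must be 'signed' or 'absolute'")
  if (!config$lp_mode %in% c("exclude", "largest-component"))
    bad("lp_mode", "must be 'exclude' or 'largest-component'")
  if (checkPaths) {
    for (f in c("node_table", "clinical")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        bad(f, "file not found")
    }
    if (is.null(config$ts_dir) || !dir.exists(config$ts_dir))
      bad("ts_dir", "directory not found")
  }
  out <- if (length(v)) do.call(rbind, v)
         else data.frame(field = character(0), problem = character(0))
  if (!nrow(out) && config$step > 0)
    attr(out, "n_levels") <-
      length(sparsityGrid(config$s_min, config$s_max, config$step))
  out
}

.stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes connectivity -> graph metrics -> null normalization -> AUC
#' -> covariate-adjusted group contrasts with FDR -> NBS -> responder
#' analysis -> connectivity-symptom correlations, writing all TSV/CSV
#' outputs plus a machine-readable JSON summary with a provenance block
#' (config echo, seed, package version, timestamp). Every stochastic
#' stage consumes a seed derived deterministically from the master seed
#' plus the stage name, so a rerun with the same config and seed is
#' identical.
#'
#' @param config list from [runConfig()] / [readRunConfig()].
#' @param cohort optionally, a ready [Cohort-class] (e.g. from
#'   [simulateCohort()]); otherwise the cohort is loaded from the
#'   config's paths.
#' @return invisibly, a list (`RunReport`) with elements `curves`,
#'   `auc`, `contrasts`, `nbs` (decrease/increase paired results),
#'   `responders`, `responderNBS`, `correlations`, `provenance`.
#' @export
runPipeline <- function(config, cohort = NULL) {
  viol <- validateConfig(config, checkPaths = is.null(cohort))
  if (nrow(viol))
    stop("pipeline stage 'validate_config' failed: ",
         paste(viol$field, viol$problem, collapse = "; "))
  if (is.null(cohort)) {
    cohort <- .stageError("load", {
      nt <- loadNodeTable(config$node_table)
      loadCohort(nt, config$clinical, config$ts_dir)
    })
  }
  grid <- sparsityGrid(config$s_min, config$s_max, config$step)
  seed <- config$rng_seed

  met <- .stageError("metrics", cohortMetrics(
    cohort, grid = grid, nNull = config$n_null,
    swapFactor = config$swap_factor,
    rngSeed = .deriveSeed(seed, "metrics"),
    lpMode = config$lp_mode, ranking = config$ranking))

  contrasts <- .stageError("group_inference", groupContrasts(met$auc))

  recs <- records(cohort)
  grp <- vapply(recs, function(r) r@group, character(1))
  ses <- vapply(recs, function(r) r@session, character(1))
  ids <- vapply(recs, function(r) r@subjectId, character(1))
  preR <- recs[grp == "SZ" & ses == "baseline"]
  postR <- recs[grp == "SZ" & ses == "post"]
  postR <- postR[match(vapply(preR, function(r) r@subjectId, character(1)),
                       vapply(postR, function(r) r@subjectId,
                              character(1)))]
  havePairs <- length(postR) >= 2 && !anyNA(vapply(postR, is.null,
                                                   logical(1)))
  nbsOut <- NULL
  responders <- NULL
  respNBS <- NULL
  corrTab <- NULL
  if (havePairs) {
    preM <- lapply(preR, subjectCorr)
    postM <- lapply(postR, subjectCorr)
    nbsOut <- .stageError("nbs", list(
      decrease = nbsPermutation(
        preM, postM, design = "paired", pThr = config$nbs_p_thr,
        nPerm = config$nbs_n_perm, direction = "greater",
        statistic = config$nbs_statistic,
        rngSeed = .deriveSeed(seed, "nbs_decrease"),
        alpha = config$fdr_alpha),
      increase = nbsPermutation(
        preM, postM, design = "paired", pThr = config$nbs_p_thr,
        nPerm = config$nbs_n_perm, direction = "less",
        statistic = config$nbs_statistic,
        rngSeed = .deriveSeed(seed, "nbs_increase"),
        alpha = config$fdr_alpha)))

    ahrsPre <- vapply(preR, function(r) r@ahrs, numeric(1))
    ahrsPost <- vapply(postR, function(r) r@ahrs, numeric(1))
    pids <- vapply(preR, function(r) r@subjectId, character(1))
    responders <- .stageError("responders",
                              classifyResponders(ahrsPre, ahrsPost, pids))

    deltas <- .stageError("responder_nbs", {
      d <- lapply(seq_along(preM), function(k) {
        dd <- fisherZ(postM[[k]]) - fisherZ(preM[[k]])
        diag(dd) <- 0
        dd
      })
      names(d) <- pids
      d
    })
    if (responders$n_resp >= 2 && responders$n_nonresp >= 2)
      respNBS <- .stageError("responder_nbs", compareResponderConnectivity(
        deltas, responders, pThr = config$nbs_p_thr,
        nPerm = config$nbs_n_perm, direction = "less",
        statistic = config$nbs_statistic,
        rngSeed = .deriveSeed(seed, "responder_nbs"),
        alpha = config$fdr_alpha))

    # symptom coupling: each edge of the significant decreasing NBS
    # components, z-reduction vs AHRS reduction
    corrTab <- .stageError("correlations", {
      sig <- Filter(function(cmp) cmp$p_perm < config$fdr_alpha,
                    nbsComponents(nbsOut$decrease))
      edges <- unique(do.call(rbind, lapply(sig, `[[`, "edges")))
      if (is.null(edges) || !nrow(edges)) NULL else {
        ab <- abbreviations(nodeTable(cohort))
        rows <- lapply(seq_len(nrow(edges)), function(e) {
          i <- edges[e, 1]; j <- edges[e, 2]
          dzRed <- vapply(seq_along(preM), function(k)
            fisherZ(preM[[k]][i, j]) - fisherZ(postM[[k]][i, j]),
            numeric(1))
          correlateWithSymptoms(dzRed, ahrsPre - ahrsPost,
                                sprintf("%s-%s", ab[i], ab[j]),
                                "d_ahrs")
        })
        do.call(rbind, rows)
      }
    })
  }

  report <- list(curves = met$curves, auc = met$auc,
                 contrasts = contrasts, nbs = nbsOut,
                 responders = responders, responderNBS = respNBS,
                 correlations = corrTab,
                 provenance = list(
                   config = unclass(config), rng_seed = seed,
                   package_version =
                     as.character(utils::packageVersion("avhnet")),
                   timestamp = format(Sys.time(), tz = "UTC")))
  if (!is.null(config$out_dir)) .writeReport(report, cohort, config)
  invisible(report)
}

.writeReport <- function(report, cohort, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write.table(report$curves, out("metric_curves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$auc, out("metric_auc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$contrasts, out("group_contrasts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  nt <- nodeTable(cohort)
  if (!is.null(report$nbs)) {
    write.table(nbsReport(report$nbs$decrease, nodeTable = nt),
                out("nbs_decrease.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(nbsReport(report$nbs$increase, nodeTable = nt),
                out("nbs_increase.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(report$responders))
    write.table(report$responders$labels, out("responder_labels.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(report$responderNBS))
    write.table(nbsReport(report$responderNBS$nbs, nodeTable = nt),
                out("responder_nbs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(report$correlations))
    write.table(report$correlations, out("edge_symptom_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    provenance = report$provenance,
    n_records = length(records(cohort)),
    n_contrasts = nrow(report$contrasts),
    significant_contrasts = report$contrasts[
      report$contrasts$p_fdr < config$fdr_alpha,
      c("metric", "contrast", "direction")],
    responder_rate = if (!is.null(report$responders))
      report$responders$rate else NULL)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(NULL)
}
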