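#' Classify patients as responders by AHRS reduction
#'
#' A patient is a responder iff the fractional AHRS reduction from
#' baseline to post-treatment, `(pre - post) / pre`, is at least 0.5
#' (boundary inclusive). The rule is a pure ratio, so classification is
#' invariant to positive rescaling of the AHRS.
#'
#' @param ahrsPre,ahrsPost paired per-patient scores; `ahrsPre` must be
#'   strictly positive.
#' @param subjectIds optional ids carried into the table.
#' @return list with `labels` (data.frame `subject_id, ahrs_pre,
#'   ahrs_post, pct_reduction, label`), `n_resp`, `n_nonresp`, and
#'   `rate` (percent responders).
#' @export
classifyResponders <- function(ahrsPre, ahrsPost, subjectIds = NULL) {
  if (length(ahrsPre) != length(ahrsPost))
    stop("pre and post scores must be paired (equal length)")
  if (any(ahrsPre <= 0))
    stop("undefined reduction: baseline AHRS must be > 0 (patient ",
         which(ahrsPre <= 0)[1], ")")
  if (is.null(subjectIds)) subjectIds <- sprintf("P%02d",
                                                 seq_along(ahrsPre))
  red <- (ahrsPre - ahrsPost) / ahrsPre
  lab <- ifelse(red >= 0.5, "responder", "non_responder")
  tab <- data.frame(subject_id = subjectIds, ahrs_pre = ahrsPre,
                    ahrs_post = ahrsPost, pct_reduction = 100 * red,
                    label = lab, stringsAsFactors = FALSE)
  nr <- sum(lab == "responder")
  list(labels = tab, n_resp = nr, n_nonresp = length(lab) - nr,
       rate = 100 * nr / length(lab))
}

#' Compare connectivity change between responders and non-responders
#'
#' Unpaired edgewise comparison of per-patient pre-to-post change
#' matrices (already on the Fisher-z scale) between the two subgroups,
#' with NBS correction at the component level.
#'
#' @param deltas list of per-patient N x N change matrices, aligned with
#'   `labels`.
#' @param labels result of [classifyResponders()] (or a character vector
#'   of `"responder"` / `"non_responder"`).
#' @param ... passed to [nbsPermutation()] (e.g. `nPerm`, `rngSeed`,
#'   `direction`, `statistic`).
#' @return list with `tMatrix` (edgewise t, responders minus
#'   non-responders) and `nbs` (an [NBSResult-class]).
#' @export
compareResponderConnectivity <- function(deltas, labels, ...) {
  lab <- if (is.list(labels) && !is.null(labels$labels))
    labels$labels$label else as.character(labels)
  if (length(lab) != length(deltas))
    stop("labels must align with the delta matrices")
  a <- deltas[lab == "responder"]
  b <- deltas[lab == "non_responder"]
  if (length(a) < 2 || length(b) < 2)
    stop("insufficient group: need at least 2 patients per subgroup")
  spread <- max(vapply(deltas, function(d) max(abs(d - deltas[[1]])),
                       numeric(1)))
  if (spread == 0)
    stop("degenerate variance: all change matrices are identical")
  tMat <- edgewiseStats(a, b, design = "unpaired", transform = "none")
  nbs <- nbsPermutation(a, b, design = "unpaired", transform = "none",
                        ...)
  list(tMatrix = tMat, nbs = nbs)
}

#' Per-patient edge change matrices (post minus baseline, Fisher z)
#'
#' @param cohort a [Cohort-class] with paired patient sessions.
#' @return named list (by subject id) of N x N z-change matrices
#'   (post - baseline).
#' @export
edgeChangeMatrices <- function(cohort) {
  recs <- records(cohort)
  grp <- vapply(recs, function(r) r@group, character(1))
  ses <- vapply(recs, function(r) r@session, character(1))
  ids <- vapply(recs, function(r) r@subjectId, character(1))
  preIdx <- which(grp == "SZ" & ses == "baseline")
  out <- list()
  for (k in preIdx) {
    j <- which(ids == ids[k] & ses == "post")
    if (!length(j)) next
    zPre <- fisherZ(subjectCorr(recs[[k]]))
    zPost <- fisherZ(subjectCorr(recs[[j]]))
    d <- zPost - zPre
    diag(d) <- 0
    out[[ids[k]]] <- d
  }
  out
}
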