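#' NodeTable: the ROI atlas driving matrix dimension and edge labels
#'
#' Ordered table of network nodes: 1-based index, anatomical label,
#' abbreviation and MNI coordinates (mm). The packaged AVH atlas has 35
#' rows; duplicate abbreviations/coordinates occur in the printed atlas
#' and are preserved, but flagged in the validation report accessible
#' via [validationReport()].
#'
#' @slot table data.frame with columns `index`, `label`, `abbrev`,
#'   `x`, `y`, `z`.
#' @slot validation data.frame of flagged anomalies (duplicate
#'   coordinates or abbreviations), columns `rows`, `issue`, `detail`.
#' @exportClass NodeTable
setClass("NodeTable",
  representation(table = "data.frame", validation = "data.frame"))

setValidity("NodeTable", function(object) {
  tab <- object@table
  need <- c("index", "label", "abbrev", "x", "y", "z")
  if (!all(need %in% names(tab)))
    return(paste("missing columns:",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  if (nrow(tab) == 0) return("node table is empty")
  if (!identical(as.integer(tab$index), seq_len(nrow(tab))))
    return("node indices must be consecutive from 1 with no gaps")
  if (any(!nzchar(trimws(tab$abbrev))))
    return("abbreviations must be non-empty")
  if (!all(vapply(tab[, c("x", "y", "z")], is.numeric, logical(1))))
    return("coordinates must be numeric")
  TRUE
})

#' SubjectRecord: one subject-session of imaging plus clinical data
#'
#' Holds either an ROI time-series matrix (T timepoints x N nodes), a
#' precomputed N x N correlation matrix, or both, together with group
#' (`HC`/`SZ`), session (`baseline`/`post`), and clinical covariates.
#' Healthy controls carry a baseline session only.
#'
#' @slot subjectId character scalar.
#' @slot group `"HC"` or `"SZ"`.
#' @slot session `"baseline"` or `"post"`.
#' @slot timeseries numeric matrix or `NULL`.
#' @slot corr numeric correlation matrix or `NULL`.
#' @slot age years; @slot sex `"male"`/`"female"`;
#'   @slot fd mean frame-wise displacement (mm).
#' @slot ahrs AHRS score (`NA` for controls).
#' @slot panss named numeric vector `pos`, `neg`, `gen`, `total`
#'   (`NA` for controls).
#' @exportClass SubjectRecord
setClass("SubjectRecord",
  representation(subjectId = "character", group = "character",
                 session = "character", timeseries = "ANY", corr = "ANY",
                 age = "numeric", sex = "character", fd = "numeric",
                 ahrs = "numeric", panss = "numeric"))

setValidity("SubjectRecord", function(object) {
  if (!object@group %in% c("HC", "SZ")) return("group must be HC or SZ")
  if (!object@session %in% c("baseline", "post"))
    return("session must be baseline or post")
  if (object@group == "HC" && object@session != "baseline")
    return("HC records carry session = baseline only")
  if (is.null(object@timeseries) && is.null(object@corr))
    return("at least one of timeseries / corr must be present")
  if (!is.null(object@corr)) {
    cm <- object@corr
    if (!is.matrix(cm) || nrow(cm) != ncol(cm))
      return("corr must be a square matrix")
    if (max(abs(cm - t(cm))) > 1e-10) return("corr must be symmetric")
    if (max(abs(diag(cm) - 1)) > 1e-10) return("corr must have unit diagonal")
  }
  if (!object@sex %in% c("male", "female"))
    return("sex must be male or female")
  TRUE
})

#' Cohort: a node table plus a list of subject records
#'
#' @slot nodeTable [NodeTable-class] object.
#' @slot records list of [SubjectRecord-class] objects whose matrix
#'   dimensions all match the node table.
#' @exportClass Cohort
setClass("Cohort",
  representation(nodeTable = "NodeTable", records = "list"))

setValidity("Cohort", function(object) {
  n <- nrow(object@nodeTable@table)
  for (r in object@records) {
    if (!is(r, "SubjectRecord")) return("records must be SubjectRecord")
    if (!is.null(r@timeseries) && ncol(r@timeseries) != n)
      return(sprintf("record %s: %d time-series columns, node table has %d",
                     r@subjectId, ncol(r@timeseries), n))
    if (!is.null(r@corr) && nrow(r@corr) != n)
      return(sprintf("record %s: %d-node matrix, node table has %d",
                     r@subjectId, nrow(r@corr), n))
  }
  TRUE
})

#' BinaryGraph: undirected unweighted adjacency at one sparsity level
#'
#' @slot adjacency symmetric 0/1 integer matrix with zero diagonal.
#' @slot sparsity retained edge fraction in (0, 1).
#' @slot edgeCount integer; equals `round(sparsity * N(N-1)/2)` and half
#'   the adjacency sum.
#' @exportClass BinaryGraph
setClass("BinaryGraph",
  representation(adjacency = "matrix", sparsity = "numeric",
                 edgeCount = "integer"))

setValidity("BinaryGraph", function(object) {
  A <- object@adjacency
  if (nrow(A) != ncol(A)) return("adjacency must be square")
  if (!all(A %in% c(0L, 1L))) return("adjacency must be 0/1")
  if (!identical(A, t(A))) return("adjacency must be symmetric")
  if (any(diag(A) != 0)) return("adjacency must have zero diagonal")
  if (sum(A) != 2L * object@edgeCount)
    return("edgeCount must equal half the adjacency sum")
  if (object@sparsity <= 0 || object@sparsity >= 1)
    return("sparsity must lie in (0, 1)")
  TRUE
})

#' NBSResult: supra-threshold components with permutation p-values
#'
#' Result of [nbsPermutation()]. Components are sorted by descending
#' statistic (extent in edges, or t-mass); each carries the edge list of
#' its supra-threshold edges and a permutation p-value from the
#' max-statistic null distribution (add-one rule, never exactly 0).
#'
#' @slot components list; each element a list with `edges` (k x 2
#'   integer matrix of 1-based node pairs), `size` (edge count),
#'   `mass` (sum of |t|), `stat` (the statistic used for inference) and
#'   `p_perm`.
#' @slot thresholdT primary edge-forming threshold on |t|.
#' @slot nPerm number of permutations.
#' @slot alpha nominal component-level significance level.
#' @slot design `"unpaired"` or `"paired"`.
#' @slot direction `"greater"` or `"less"`.
#' @slot statistic `"extent"` or `"intensity"`.
#' @slot nullMax numeric vector of the permutation max statistics.
#' @exportClass NBSResult
setClass("NBSResult",
  representation(components = "list", thresholdT = "numeric",
                 nPerm = "integer", alpha = "numeric", design = "character",
                 direction = "character", statistic = "character",
                 nullMax = "numeric"))

setValidity("NBSResult", function(object) {
  for (cmp in object@components) {
    if (cmp$p_perm <= 0 || cmp$p_perm > 1)
      return("p_perm must lie in (0, 1]")
  }
  if (length(object@components) > 1) {
    s <- vapply(object@components, function(x) x$stat, numeric(1))
    if (is.unsorted(rev(s))) return("components must be sorted descending")
  }
  TRUE
})
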