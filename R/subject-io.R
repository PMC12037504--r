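#' Load an ROI time-series matrix
#'
#' Plain-text matrix, one timepoint per row, one column per node
#' (whitespace- or comma-delimited, no header). The column count must
#' match the node table; constant (zero-variance) columns are flagged
#' with a warning, as are series shorter than 30 timepoints (correlation
#' estimates degrade, but short series are accepted).
#'
#' @param path file path.
#' @param nodeTable a [NodeTable-class] fixing the expected column count.
#' @return numeric T x N matrix with node abbreviations as column names.
#' @export
loadTimeseries <- function(path, nodeTable) {
  stopifnot(is(nodeTable, "NodeTable"))
  if (!file.exists(path)) stop("time-series file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  ts <- as.matrix(read.table(path, header = FALSE, sep = sep))
  n <- nodeCount(nodeTable)
  if (ncol(ts) != n)
    stop(sprintf("dimension error: %s has %d columns, node table expects %d",
                 basename(path), ncol(ts), n))
  storage.mode(ts) <- "double"
  dimnames(ts) <- list(NULL, abbreviations(nodeTable))
  if (nrow(ts) < 30)
    warning(sprintf("time series has only %d timepoints (< 30); ",
                    nrow(ts)),
            "correlation estimates will be unstable")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0))
    warning("constant (zero-variance) column(s): ",
            paste(which(sds == 0), collapse = ", "))
  ts
}

#' Write an ROI time-series matrix
#'
#' @param ts numeric T x N matrix.
#' @param path output file (tab-separated, full precision, no header).
#' @return `path`, invisibly.
#' @export
writeTimeseries <- function(ts, path) {
  write.table(format(ts, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract spherical-ROI mean time series from a 4D NIfTI volume
#'
#' For each atlas node, averages the signal over voxels whose MNI
#' coordinates (via the image affine) fall within `radius` mm of the
#' node's coordinate. Spheres of radius 6 mm are the field convention
#' for coordinate-defined nodes; the radius is configurable. Nodes whose
#' sphere contains no voxel produce an all-zero column and a warning.
#'
#' @param path path to a 4D NIfTI-1 image (.nii/.nii.gz) with an affine
#'   mapping voxel indices to MNI mm.
#' @param nodeTable a [NodeTable-class].
#' @param radius sphere radius in mm (> 0), default 6.
#' @return T x N matrix with attribute `voxel_counts` (contributing
#'   voxels per node).
#' @export
extractRoiTimeseries <- function(path, nodeTable, radius = 6) {
  stopifnot(is(nodeTable, "NodeTable"), radius > 0)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4) stop("expected a 4D volume, got ", length(dm), "D")
  aff <- RNifti::xform(img)
  tab <- as.data.frame(nodeTable)
  n <- nrow(tab)
  tlen <- dm[4]
  # voxel-center world coordinates (RNifti xforms are 0-based)
  grid <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1,
                                j = seq_len(dm[2]) - 1,
                                k = seq_len(dm[3]) - 1))
  world <- cbind(grid, 1) %*% t(aff)
  out <- matrix(0, tlen, n, dimnames = list(NULL, tab$abbrev))
  counts <- integer(n)
  vol <- array(img, dim = dm)
  vmat <- matrix(vol, nrow = prod(dm[1:3]), ncol = tlen)
  for (jn in seq_len(n)) {
    d2 <- (world[, 1] - tab$x[jn])^2 + (world[, 2] - tab$y[jn])^2 +
      (world[, 3] - tab$z[jn])^2
    inside <- which(d2 <= radius^2)
    counts[jn] <- length(inside)
    if (!length(inside)) {
      warning(sprintf("node %d (%s): no voxels within %.2f mm", jn,
                      tab$abbrev[jn], radius))
      next
    }
    out[, jn] <- colMeans(vmat[inside, , drop = FALSE])
  }
  attr(out, "voxel_counts") <- counts
  out
}

#' Load a clinical table as subject-record stubs
#'
#' CSV with header `subject_id, group, session, age, sex, fd, ahrs,
#' panss_pos, panss_neg, panss_gen, panss_total`. Returns one
#' [SubjectRecord-class] stub per row (no imaging data attached yet);
#' patient pre/post rows are paired by `subject_id`.
#'
#' @param path CSV file path.
#' @return list of [SubjectRecord-class] stubs (empty for a header-only
#'   file).
#' @export
loadClinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "session", "age", "sex", "fd", "ahrs",
            "panss_pos", "panss_neg", "panss_gen", "panss_total")
  if (!all(need %in% names(tab)))
    stop("clinical format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (nrow(tab) == 0) return(list())
  key <- paste(tab$subject_id, tab$session)
  if (anyDuplicated(key))
    stop("uniqueness error: duplicate (subject_id, session): ",
         key[duplicated(key)][1])
  post <- tab$subject_id[tab$session == "post"]
  base <- tab$subject_id[tab$session == "baseline"]
  orphan <- setdiff(post, base)
  if (length(orphan))
    stop("pairing error: post session without baseline for subject(s) ",
         paste(orphan, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    new("SubjectRecord",
        subjectId = as.character(row$subject_id), group = row$group,
        session = row$session,
        # stub: a 1x1 placeholder satisfies "imaging present" until data
        # are attached; attachTimeseries() replaces it
        timeseries = matrix(0, 1, 1), corr = NULL,
        age = as.numeric(row$age), sex = row$sex, fd = as.numeric(row$fd),
        ahrs = as.numeric(row$ahrs),
        panss = c(pos = as.numeric(row$panss_pos),
                  neg = as.numeric(row$panss_neg),
                  gen = as.numeric(row$panss_gen),
                  total = as.numeric(row$panss_total)))
  })
}

#' Write a cohort's clinical table to CSV
#'
#' @param cohort a [Cohort-class] (or list of [SubjectRecord-class]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(cohort, path) {
  recs <- if (is(cohort, "Cohort")) records(cohort) else cohort
  rows <- lapply(recs, function(r) data.frame(
    subject_id = r@subjectId, group = r@group, session = r@session,
    age = r@age, sex = r@sex, fd = r@fd, ahrs = r@ahrs,
    panss_pos = r@panss[["pos"]], panss_neg = r@panss[["neg"]],
    panss_gen = r@panss[["gen"]], panss_total = r@panss[["total"]],
    stringsAsFactors = FALSE))
  write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Assemble a cohort from clinical stubs and per-subject time-series files
#'
#' Time-series files follow the pattern `<subject_id>_<session>.tsv`
#' inside `tsDir`.
#'
#' @param nodeTable a [NodeTable-class].
#' @param clinicalPath clinical CSV (see [loadClinical()]).
#' @param tsDir directory of time-series files.
#' @return a [Cohort-class].
#' @export
loadCohort <- function(nodeTable, clinicalPath, tsDir) {
  stubs <- loadClinical(clinicalPath)
  recs <- lapply(stubs, function(r) {
    f <- file.path(tsDir, sprintf("%s_%s.tsv", r@subjectId, r@session))
    if (!file.exists(f))
      stop("missing time-series file for ", r@subjectId, " (", r@session,
           "): ", f)
    r@timeseries <- loadTimeseries(f, nodeTable)
    r
  })
  new("Cohort", nodeTable = nodeTable, records = recs)
}
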