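#' Load a node table (ROI atlas)
#'
#' Reads a tab- or comma-separated file with header columns
#' `index, label, abbrev, x, y, z` into a [NodeTable-class]. The packaged
#' AVH atlas (`system.file("extdata", "avh_node_table.tsv", package =
#' "avhnet")`) has 35 regions with MNI coordinates; its printed anomalies
#' (duplicate coordinates and abbreviations) are preserved verbatim and
#' listed in the validation report.
#'
#' @param path file path.
#' @param dedupe if `TRUE`, collapse exact-coordinate duplicate rows
#'   (keeping the first) and re-index; default `FALSE`, fidelity to the
#'   printed atlas.
#' @return a [NodeTable-class]; `validationReport()` lists duplicate
#'   coordinates/abbreviations.
#' @export
loadNodeTable <- function(path, dedupe = FALSE) {
  if (!file.exists(path)) stop("node table file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, quote = "\"",
                    colClasses = "character", comment.char = "")
  names(tab) <- tolower(trimws(names(tab)))
  need <- c("index", "label", "abbrev", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("node table format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab <- tab[, need]
  for (cc in c("index", "x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & !is.na(tab[[cc]]))
    if (length(bad))
      stop(sprintf("node table parse error: non-numeric '%s' in row %d (%s)",
                   cc, bad[1], tab[[cc]][bad[1]]))
    tab[[cc]] <- v
  }
  tab$index <- as.integer(tab$index)
  if (dedupe) {
    key <- paste(tab$x, tab$y, tab$z)
    tab <- tab[!duplicated(key), , drop = FALSE]
    tab$index <- seq_len(nrow(tab))
  }
  rownames(tab) <- NULL
  new("NodeTable", table = tab, validation = .nodeTableValidation(tab))
}

.nodeTableValidation <- function(tab) {
  rep <- data.frame(rows = character(0), issue = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  key <- paste(tab$x, tab$y, tab$z)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    rep <- rbind(rep, data.frame(
      rows = paste(idx, collapse = ","), issue = "duplicate_coordinates",
      detail = sprintf("(%g,%g,%g)", tab$x[idx[1]], tab$y[idx[1]],
                       tab$z[idx[1]]), stringsAsFactors = FALSE))
  }
  ab <- tab$abbrev
  for (a in unique(ab[duplicated(ab)])) {
    idx <- which(ab == a)
    rep <- rbind(rep, data.frame(
      rows = paste(idx, collapse = ","), issue = "duplicate_abbreviation",
      detail = a, stringsAsFactors = FALSE))
  }
  rep
}

#' Write a node table back to disk
#'
#' @param x a [NodeTable-class].
#' @param path output file; tab-separated with the canonical header.
#' @return `path`, invisibly.
#' @export
writeNodeTable <- function(x, path) {
  stopifnot(is(x, "NodeTable"))
  write.table(x@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged 35-region AVH atlas
#'
#' Convenience loader for the atlas shipped with the package.
#' @inheritParams loadNodeTable
#' @return a [NodeTable-class] with 35 rows (fewer when `dedupe = TRUE`).
#' @export
avhNodeTable <- function(dedupe = FALSE) {
  loadNodeTable(system.file("extdata", "avh_node_table.tsv",
                            package = "avhnet", mustWork = TRUE),
                dedupe = dedupe)
}

#' Node-to-module assignment for the packaged atlas
#'
#' Maps each atlas node (by index) to one of five anatomical modules
#' (`temporal`, `prefrontal`, `subcortical`, `parietal`, `visual`) used
#' by the synthetic cohort generator's block covariance. The mapping is
#' a packaged, editable TSV keyed by node index (abbreviations are not
#' unique in the printed atlas).
#'
#' @return character vector of module names, length 35, named by node
#'   abbreviation.
#' @export
avhNodeModules <- function() {
  path <- system.file("extdata", "avh_node_modules.tsv",
                      package = "avhnet", mustWork = TRUE)
  mp <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  setNames(mp$module, mp$abbrev)
}
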