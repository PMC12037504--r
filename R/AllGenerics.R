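#' @name avhnet-accessors
#' @title Accessors for avhnet S4 classes
#' @description Slot access for [NodeTable-class], [Cohort-class] and
#'   [BinaryGraph-class] objects goes through these generics; slots are
#'   internal.
#' @param x an avhnet S4 object.
#' @return See the individual methods.
NULL

#' @rdname avhnet-accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname avhnet-accessors
#' @export
setGeneric("abbreviations", function(x) standardGeneric("abbreviations"))

#' @rdname avhnet-accessors
#' @export
setGeneric("validationReport", function(x) standardGeneric("validationReport"))

#' @rdname avhnet-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname avhnet-accessors
#' @export
setGeneric("sparsity", function(x) standardGeneric("sparsity"))

#' @rdname avhnet-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname avhnet-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname avhnet-accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname avhnet-accessors
#' @export
setGeneric("nbsComponents", function(x) standardGeneric("nbsComponents"))

setMethod("nodeCount", "NodeTable", function(x) nrow(x@table))
setMethod("nodeCount", "Cohort", function(x) nrow(x@nodeTable@table))
setMethod("abbreviations", "NodeTable", function(x) x@table$abbrev)
setMethod("validationReport", "NodeTable", function(x) x@validation)
setMethod("adjacency", "BinaryGraph", function(x) x@adjacency)
setMethod("sparsity", "BinaryGraph", function(x) x@sparsity)
setMethod("edgeCount", "BinaryGraph", function(x) x@edgeCount)
setMethod("records", "Cohort", function(x) x@records)
setMethod("nodeTable", "Cohort", function(x) x@nodeTable)
setMethod("nbsComponents", "NBSResult", function(x) x@components)

#' @export
#' @describeIn avhnet-accessors node table as a plain data.frame
#' @param row.names,optional,... passed through (unused).
as.data.frame.NodeTable <- function(x, row.names = NULL, optional = FALSE, ...)
  x@table

setMethod("show", "NodeTable", function(object) {
  cat(sprintf("NodeTable with %d nodes\n", nrow(object@table)))
  print(head(object@table, 4))
  if (nrow(object@table) > 4) cat("  ...\n")
  if (nrow(object@validation))
    cat(sprintf("  %d flagged anomalies (validationReport())\n",
                nrow(object@validation)))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s [%s, %s] ts:%s corr:%s\n",
              object@subjectId, object@group, object@session,
              if (is.null(object@timeseries)) "-" else
                paste(dim(object@timeseries), collapse = "x"),
              if (is.null(object@corr)) "-" else
                paste(dim(object@corr), collapse = "x")))
})

setMethod("show", "Cohort", function(object) {
  grp <- vapply(object@records, function(r) r@group, character(1))
  ses <- vapply(object@records, function(r) r@session, character(1))
  cat(sprintf(
    "Cohort: %d nodes, %d records (HC %d, SZ baseline %d, SZ post %d)\n",
    nodeCount(object), length(object@records), sum(grp == "HC"),
    sum(grp == "SZ" & ses == "baseline"), sum(grp == "SZ" & ses == "post")))
})

setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph: %d nodes, %d edges (sparsity %.3f)\n",
              nrow(object@adjacency), object@edgeCount, object@sparsity))
})

setMethod("show", "NBSResult", function(object) {
  cat(sprintf(
    "NBSResult (%s, %s, %s stat): t > %.3f, %d permutations\n",
    object@design, object@direction, object@statistic,
    object@thresholdT, object@nPerm))
  if (!length(object@components)) {
    cat("  no supra-threshold components\n")
  } else {
    for (k in seq_along(object@components)) {
      cmp <- object@components[[k]]
      cat(sprintf("  component %d: %d edges, mass %.2f, p_perm = %.4g\n",
                  k, cmp$size, cmp$mass, cmp$p_perm))
    }
  }
})
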