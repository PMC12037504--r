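#' Residualize values on nuisance covariates
#'
#' Least-squares residuals after regressing per-subject values on an
#' intercept plus covariates (typically age, sex and mean frame-wise
#' displacement). Sex is coded male = 1, female = 0 when supplied as
#' character. Group comparisons on these residuals implement the
#' "covariate-adjusted" contrasts (equivalent to the group term of an
#' ANCOVA up to degrees-of-freedom bookkeeping).
#'
#' @param values numeric vector, one value per subject.
#' @param covariates data.frame or matrix of covariates (no intercept
#'   column; one is added).
#' @return numeric residual vector (sums to ~0).
#' @export
residualize <- function(values, covariates) {
  X <- .designMatrix(covariates)
  if (nrow(X) != length(values))
    stop("covariates must have one row per value")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinearity error: rank-deficient design, offending column(s): ",
         paste(drop, collapse = ", "))
  }
  as.numeric(qr.resid(qrX, values))
}

.designMatrix <- function(covariates) {
  cv <- as.data.frame(covariates)
  for (nm in names(cv)) {
    if (is.character(cv[[nm]]) || is.factor(cv[[nm]])) {
      v <- as.character(cv[[nm]])
      if (all(v %in% c("male", "female"))) {
        cv[[nm]] <- as.numeric(v == "male")  # male = 1, female = 0
      } else {
        cv[[nm]] <- as.numeric(factor(v))
      }
    }
  }
  cbind(intercept = 1, as.matrix(cv))
}

#' Two-sample and paired t tests on metric AUCs
#'
#' Student (pooled-variance) two-sample t test, or paired t test on
#' within-subject differences. Inputs with (pooled) zero variance raise
#' a degenerate-variance error rather than returning NaN.
#'
#' @param a,b numeric vectors (paired: equal length, aligned by
#'   subject).
#' @param metric,contrast labels carried into the result row.
#' @return one-row data.frame `metric, contrast, t, df, p_raw,
#'   direction` (direction = sign of mean(a) - mean(b)).
#' @export
twoSampleTest <- function(a, b, metric = "", contrast = "") {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per group")
  if (var(a) == 0 && var(b) == 0)
    stop("degenerate variance: both groups are constant")
  ht <- t.test(a, b, var.equal = TRUE)
  data.frame(metric = metric, contrast = contrast,
             t = unname(ht$statistic), df = unname(ht$parameter),
             p_raw = ht$p.value,
             direction = sign(mean(a) - mean(b)),
             stringsAsFactors = FALSE)
}

#' @rdname twoSampleTest
#' @param pre,post paired numeric vectors.
#' @export
pairedTest <- function(pre, post, metric = "", contrast = "") {
  if (length(pre) != length(post))
    stop("paired inputs must have equal length")
  if (length(pre) < 2) stop("need at least 2 pairs")
  d <- post - pre
  if (sd(d) == 0)
    stop("degenerate variance: zero variance of paired differences")
  ht <- t.test(d)
  data.frame(metric = metric, contrast = contrast,
             t = unname(ht$statistic), df = unname(ht$parameter),
             p_raw = ht$p.value, direction = sign(mean(d)),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone after sorting, capped at 1).
#' Validates the input range, then delegates to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
fdrBH <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("validation error: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson correlation between change scores
#'
#' Correlates a per-patient connectivity change with a per-patient
#' symptom change (e.g. edge z-change vs AHRS reduction); two-sided p
#' via the t transform.
#'
#' @param xChange,yChange paired numeric vectors, n >= 3.
#' @param xName,yName labels.
#' @return one-row data.frame `x, y, n, r, p`.
#' @export
correlateWithSymptoms <- function(xChange, yChange, xName = "x",
                                  yName = "y") {
  keep <- complete.cases(xChange, yChange)
  x <- xChange[keep]; y <- yChange[keep]
  if (length(x) < 3) stop("correlation needs n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate variance: constant input to correlation")
  ht <- cor.test(x, y)
  data.frame(x = xName, y = yName, n = length(x),
             r = unname(ht$estimate), p = ht$p.value,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted group contrasts of AUC metrics with FDR
#'
#' Runs the three contrasts the analysis design calls for
#' (`HC_vs_pre`, `HC_vs_post`, `pre_vs_post`) for each metric AUC:
#' unpaired contrasts residualize on age, sex and FD pooled over the two
#' groups, then apply a Student t test to the residuals; the paired
#' contrast tests the intercept of `lm(diff ~ centered covariates)`
#' with the FD difference as the motion covariate (residualizing the
#' differences outright would remove the tested mean). BH-FDR is
#' applied across the whole metric x contrast family of one run.
#'
#' @param aucTab data.frame from [cohortMetrics()]`$auc`.
#' @param metrics metric AUC columns to test.
#' @param adjustCovariates include age/sex/FD adjustment (default TRUE).
#' @return data.frame `metric, contrast, t, df, p_raw, p_fdr,
#'   direction`.
#' @export
groupContrasts <- function(aucTab,
    metrics = c("cp", "lp", "eloc", "eglob", "gamma", "lambda", "sigma"),
    adjustCovariates = TRUE) {
  hc <- aucTab[aucTab$group == "HC", , drop = FALSE]
  pre <- aucTab[aucTab$group == "SZ" & aucTab$session == "baseline", ,
                drop = FALSE]
  post <- aucTab[aucTab$group == "SZ" & aucTab$session == "post", ,
                 drop = FALSE]
  post <- post[match(pre$subject_id, post$subject_id), , drop = FALSE]
  rows <- list()
  dropConstant <- function(cov) {
    keep <- vapply(cov, function(x) length(unique(x)) > 1, logical(1))
    cov[, keep, drop = FALSE]
  }
  unpaired <- function(ga, gb, mname, label) {
    va <- ga[[mname]]; vb <- gb[[mname]]
    if (adjustCovariates) {
      cov <- dropConstant(rbind(ga[, c("age", "sex", "fd")],
                                gb[, c("age", "sex", "fd")]))
      if (ncol(cov) && nrow(cov) > ncol(cov) + 2) {
        res <- residualize(c(va, vb), cov)
        va <- res[seq_along(ga[[mname]])]
        vb <- res[-seq_along(ga[[mname]])]
      }
    }
    twoSampleTest(va, vb, mname, label)
  }
  for (mname in metrics) {
    rows[[length(rows) + 1]] <- unpaired(hc, pre, mname, "HC_vs_pre")
    if (nrow(post) && !anyNA(post$subject_id)) {
      rows[[length(rows) + 1]] <- unpaired(hc, post, mname, "HC_vs_post")
      d <- post[[mname]] - pre[[mname]]
      X <- NULL
      if (adjustCovariates) {
        cov <- dropConstant(data.frame(age = pre$age, sex = pre$sex,
                                       dfd = post$fd - pre$fd))
        if (ncol(cov)) {
          X <- .designMatrix(cov)
          X[, -1] <- scale(X[, -1, drop = FALSE], center = TRUE,
                           scale = FALSE)
          qrX <- qr(X)
          X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
          if (length(d) - ncol(X) < 2) X <- NULL  # too few pairs to adjust
        }
      }
      if (is.null(X)) {
        rows[[length(rows) + 1]] <- pairedTest(pre[[mname]], post[[mname]],
                                               mname, "pre_vs_post")
      } else {
        # mean change adjusted for centered covariates: the intercept t
        fit <- lm.fit(X, d)
        rdf <- length(d) - ncol(X)
        se <- sqrt(sum(fit$residuals^2) / rdf *
                     chol2inv(chol(crossprod(X)))[1, 1])
        tval <- fit$coefficients[1] / se
        rows[[length(rows) + 1]] <- data.frame(
          metric = mname, contrast = "pre_vs_post", t = unname(tval),
          df = rdf, p_raw = 2 * pt(-abs(tval), rdf),
          direction = sign(mean(d)), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- fdrBH(out$p_raw)
  out[, c("metric", "contrast", "t", "df", "p_raw", "p_fdr", "direction")]
}
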