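#' Pool study-level log hazard ratios
#'
#' Fixed effect: inverse-variance weights w_i = 1/se_i^2. Random effects:
#' DerSimonian-Laird tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))
#' with re-weighting w*_i = 1/(se_i^2 + tau^2). Cochran's Q and I^2 are
#' always reported from the fixed-effect weights, so a random-effects
#' result with Q <= df collapses to the fixed-effect one exactly.
#'
#' @param studies data.frame of study effects with \code{log_hr} and
#'   \code{se} (> 0) columns, e.g. from \code{\link{readMetaTable}} or
#'   \code{\link{generateMetaStudies}}.
#' @param method \code{"random-DL"} (default) or \code{"fixed"}.
#' @param subgroup optional tag; when given, studies are filtered to
#'   \code{studies$subgroup == subgroup} before pooling.
#' @return a \code{\linkS4class{MetaResult}}.
#' @export
poolEffects <- function(studies, method = c("random-DL", "fixed"),
                        subgroup = NULL) {
  method <- match.arg(method)
  if (!is.null(subgroup)) {
    if (!"subgroup" %in% colnames(studies))
      stop("studies carry no subgroup column")
    studies <- studies[studies$subgroup == subgroup, , drop = FALSE]
  }
  k <- nrow(studies)
  if (k == 0L) stop("no studies left after filtering")
  if (any(studies$se <= 0)) stop("se must be > 0")
  d <- studies$log_hr
  w <- 1 / studies$se^2
  pooledFixed <- sum(w * d) / sum(w)
  Q <- sum(w * (d - pooledFixed)^2)
  df <- k - 1
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  if (method == "fixed") {
    new("MetaResult", method = "fixed", pooledLogHR = pooledFixed,
        pooledSE = sqrt(1 / sum(w)), Q = Q, df = as.numeric(df), i2 = i2,
        tau2 = 0, k = as.integer(k))
  } else {
    c2 <- sum(w) - sum(w^2) / sum(w)
    tau2 <- if (df > 0 && c2 > 0) max(0, (Q - df) / c2) else 0
    ws <- 1 / (studies$se^2 + tau2)
    new("MetaResult", method = "random-DL",
        pooledLogHR = sum(ws * d) / sum(ws), pooledSE = sqrt(1 / sum(ws)),
        Q = Q, df = as.numeric(df), i2 = i2, tau2 = tau2,
        k = as.integer(k))
  }
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the studies k times, omitting one study per row.
#'
#' @param studies study data.frame (k >= 2).
#' @param method passed to \code{\link{poolEffects}}.
#' @return data.frame keyed by \code{omitted} study id with the pooled
#'   log HR, SE, HR, 95\% CI, and heterogeneity of each reduced pooling.
#' @export
leaveOneOut <- function(studies, method = c("random-DL", "fixed")) {
  method <- match.arg(method)
  k <- nrow(studies)
  if (k < 2L) stop("need >= 2 studies for leave-one-out")
  rows <- lapply(seq_len(k), function(i) {
    res <- poolEffects(studies[-i, , drop = FALSE], method = method)
    ci <- confint95(res)
    data.frame(omitted = studies$study_id[i],
               pooled_log_hr = pooledLogHR(res), pooled_se = pooledSE(res),
               hr = pooledHR(res), ci_lower = ci[["lower"]],
               ci_upper = ci[["upper"]], Q = res@Q, i2 = res@i2,
               tau2 = res@tau2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect (log_hr_i / se_i) on
#' precision (1 / se_i); the intercept estimates small-study asymmetry.
#' Two-sided p from the t distribution at k - 2 df. Requires k >= 3 and
#' non-degenerate (non-constant) precisions.
#'
#' @param studies study data.frame with \code{log_hr}, \code{se}.
#' @return list with \code{intercept}, \code{intercept_se}, \code{t},
#'   \code{p}, \code{k}, and \code{funnel} (data.frame of \code{log_hr} /
#'   \code{se} coordinates for funnel plotting).
#' @export
eggerTest <- function(studies) {
  k <- nrow(studies)
  if (k < 3L) stop("Egger's test needs >= 3 studies")
  prec <- 1 / studies$se
  if (max(prec) - min(prec) < .Machine$double.eps * 100)
    stop("all standard errors equal; precision regressor is degenerate")
  fit <- lm(I(studies$log_hr / studies$se) ~ prec)
  # a perfect fit (constant true effect) is a legitimate input here
  sm <- suppressWarnings(summary(fit))$coefficients
  intercept <- sm["(Intercept)", "Estimate"]
  se <- sm["(Intercept)", "Std. Error"]
  tstat <- intercept / se
  list(intercept = intercept, intercept_se = se, t = tstat,
       p = 2 * pt(-abs(tstat), df = k - 2), k = k,
       funnel = data.frame(study_id = studies$study_id,
                           log_hr = studies$log_hr, se = studies$se,
                           stringsAsFactors = FALSE))
}
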