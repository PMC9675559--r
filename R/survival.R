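#' Kaplan-Meier product-limit estimate
#'
#' Wraps \code{survival::survfit}; censored times reduce the risk set
#' without introducing steps.
#'
#' @param records data.frame with \code{os_time} and \code{os_event}
#'   columns (e.g. a validated clinical table), >= 1 record.
#' @return data.frame with \code{time} (ascending event/censoring times),
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv}
#'   (non-increasing from 1).
#' @export
kaplanMeier <- function(records) {
  if (!nrow(records)) stop("no survival records")
  fit <- survival::survfit(
    survival::Surv(os_time, os_event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic summed over distinct event
#' times with hypergeometric variance (via \code{survival::survdiff},
#' rho = 0); p from the chi-square upper tail at df = groups - 1.
#'
#' @param records data.frame with \code{sample_id}, \code{os_time},
#'   \code{os_event}.
#' @param groups named character vector, sample_id -> group; >= 2 non-empty
#'   groups, every record covered.
#' @return list with \code{chi2}, \code{df}, \code{p}, \code{n} (per-group
#'   sizes), \code{observed}, \code{expected}.
#' @export
logrankTest <- function(records, groups) {
  missing <- setdiff(records$sample_id, names(groups))
  if (length(missing))
    stop(sprintf("record(s) without group: %s",
                 paste(missing, collapse = ", ")))
  g <- factor(groups[records$sample_id])
  if (nlevels(g) < 2L) stop("need >= 2 non-empty groups")
  if (any(table(g) == 0L)) stop("a group has zero subjects")
  sd <- survival::survdiff(
    survival::Surv(records$os_time, records$os_event) ~ g, rho = 0)
  df <- nlevels(g) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE),
       n = setNames(as.vector(sd$n), levels(g)),
       observed = setNames(as.vector(sd$obs), levels(g)),
       expected = setNames(as.vector(sd$exp), levels(g)))
}

# Dunn's post-hoc z statistics on rank sums with tie correction
dunnPosthoc <- function(values, g, adjust = "BH") {
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  meanRank <- tapply(r, g, mean)
  nG <- tapply(r, g, length)
  pairs <- combn(lev, 2L)
  z <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    (meanRank[i] - meanRank[j]) /
      sqrt((N * (N + 1) / 12 - tieCorr) * (1 / nG[i] + 1 / nG[j]))
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             statistic = unname(z), p = unname(p),
             p_adj = unname(p.adjust(p, method = adjust)),
             stringsAsFactors = FALSE)
}

#' Two-or-more-group comparison of a continuous score
#'
#' \code{"t"}: two-sided pooled-variance Student's t test.
#' \code{"mann-whitney"}: two-sided Mann-Whitney U (Wilcoxon rank-sum).
#' \code{"anova-tukey"}: one-way ANOVA with Tukey HSD pairwise comparisons.
#' \code{"kruskal-dunn"}: Kruskal-Wallis with Dunn's pairwise post hoc
#' (BH-adjusted by default). Two-group methods reject >= 3 groups and vice
#' versa.
#'
#' @param values numeric vector of per-sample scores.
#' @param groups group labels aligned with \code{values}.
#' @param method one of \code{"t"}, \code{"mann-whitney"},
#'   \code{"anova-tukey"}, \code{"kruskal-dunn"}.
#' @param adjust p adjustment for Dunn's post hoc.
#' @return list with \code{method}, \code{statistic}, \code{p}, and for the
#'   omnibus methods a \code{pairwise} data.frame of adjusted comparisons.
#' @export
compareGroups <- function(values, groups,
                          method = c("t", "mann-whitney", "anova-tukey",
                                     "kruskal-dunn"),
                          adjust = "BH") {
  method <- match.arg(method)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  two <- method %in% c("t", "mann-whitney")
  if (two && nlevels(g) != 2L)
    stop(sprintf("method '%s' requires exactly 2 groups, got %d",
                 method, nlevels(g)))
  if (!two && nlevels(g) < 3L)
    stop(sprintf("method '%s' requires >= 3 groups", method))
  if (method == "t" && any(table(g) < 2L))
    stop("each group needs >= 2 values for the t test")
  switch(method,
    "t" = {
      tt <- t.test(values ~ g, var.equal = TRUE)
      list(method = method, statistic = unname(tt$statistic),
           p = tt$p.value)
    },
    "mann-whitney" = {
      wt <- suppressWarnings(wilcox.test(values ~ g, exact = FALSE,
                                         correct = FALSE))
      list(method = method, statistic = unname(wt$statistic),
           p = wt$p.value)
    },
    "anova-tukey" = {
      fit <- aov(values ~ g)
      an <- summary(fit)[[1L]]
      tk <- TukeyHSD(fit)$g
      list(method = method, statistic = an$`F value`[1L],
           p = an$`Pr(>F)`[1L],
           pairwise = data.frame(
             comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE))
    },
    "kruskal-dunn" = {
      kt <- kruskal.test(values, g)
      list(method = method, statistic = unname(kt$statistic),
           p = kt$p.value, pairwise = dunnPosthoc(values, g, adjust))
    })
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic sum((O - E)^2 / E), no continuity correction by
#' default; df = (r - 1)(c - 1). All-zero rows or columns are an error.
#'
#' @param table matrix of non-negative counts, at least 2 x 2.
#' @param correct apply Yates continuity correction (2 x 2 only).
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
chisqIndependence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all-zero row or column")
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
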