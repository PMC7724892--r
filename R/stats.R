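# Downstream group statistics: two-group t tests / one-way ANOVA with
# explicit Bonferroni family sizes, the quartile-based cognitive-decline
# contrast, and eigengene projection into external cohorts.

.statResult <- function(test, statistic, p, m, groups, means, sizes) {
  data.frame(test = test, statistic = statistic, raw_p = p,
             adjusted_p = .bonferroni(p, m), m = m,
             groups = paste(groups, collapse = "|"),
             group_means = paste(signif(means, 6), collapse = "|"),
             group_sizes = paste(sizes, collapse = "|"),
             stringsAsFactors = FALSE)
}

#' Compare group means with Bonferroni adjustment
#'
#' Two groups: two-sided Welch (unequal-variance) two-sample t test; more
#' than two groups: one-way ANOVA F test. The Bonferroni family size `m`
#' is reported explicitly alongside the adjusted p-value
#' (`adjusted_p = min(1, m * raw_p)`), because the family is defined by
#' the calling analysis, not by this function.
#'
#' @param values numeric vector of observations.
#' @param labels group labels aligned with `values` (>= 2 groups, each
#'   with >= 2 observations).
#' @param familySize Bonferroni family size `m` (default 1).
#' @param pooled use the pooled-variance t test instead of Welch
#'   (default FALSE).
#' @return One-row data.frame: `test`, `statistic`, `raw_p`, `adjusted_p`,
#'   `m`, `groups`, `group_means`, `group_sizes`.
#' @examples
#' groupCompare(c(1, 2, 3, 4, 3, 4, 5, 6), rep(c("a", "b"), each = 4))
#' @export
groupCompare <- function(values, labels, familySize = 1L, pooled = FALSE) {
  stopifnot(length(values) == length(labels))
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- factor(labels[ok])
  sizes <- table(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  means <- tapply(values, labels, mean)
  if (nlevels(labels) == 2L) {
    g1 <- values[labels == levels(labels)[1L]]
    g2 <- values[labels == levels(labels)[2L]]
    if (stats::sd(g1) < 1e-12 && stats::sd(g2) < 1e-12) {
      # degenerate null case: identical constant groups carry no evidence
      stat <- 0; p <- 1
      if (abs(mean(g1) - mean(g2)) > 1e-12)
        stop("groups are constant but unequal; the t test is undefined")
    } else {
      tt <- stats::t.test(g1, g2, var.equal = pooled)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    return(.statResult(if (pooled) "t" else "welch_t", stat, p,
                       familySize, levels(labels), means, sizes))
  }
  fit <- stats::aov(values ~ labels)
  s <- summary(fit)[[1L]]
  .statResult("anova_F", s[["F value"]][1L], s[["Pr(>F)"]][1L],
              familySize, levels(labels), means, sizes)
}

#' Quartile-split cognitive-decline contrast
#'
#' Compares MMSE decline (first minus last score, so larger = steeper
#' decline) between subjects in the lowest expression quartile ("fourth
#' quartile" of expression) and the highest ("first quartile"). Quartile
#' boundaries are the empirical 25th/75th percentiles with linear
#' interpolation; subjects exactly on a boundary fall into the inner
#' (non-extreme) group. A Welch t test compares decline between the two
#' quartile groups.
#'
#' @param expression per-subject module (or gene) expression summary.
#' @param mmseFirst MMSE at first diagnosis, aligned with `expression`.
#' @param mmseLast last valid MMSE, aligned.
#' @param familySize Bonferroni family size `m` (default 1).
#' @return One-row data.frame as in [groupCompare()], groups labelled
#'   `low_expr` / `high_expr`; attribute `"membership"` holds the
#'   per-subject quartile assignment (`low`, `mid`, `high`).
#' @export
quartileDeclineContrast <- function(expression, mmseFirst, mmseLast,
                                    familySize = 1L) {
  n <- length(expression)
  stopifnot(length(mmseFirst) == n, length(mmseLast) == n)
  if (n < 8L) stop("need at least 8 subjects")
  decline <- mmseFirst - mmseLast
  qs <- stats::quantile(expression, c(0.25, 0.75), type = 7, names = FALSE)
  memb <- ifelse(expression < qs[1L], "low",
          ifelse(expression > qs[2L], "high", "mid"))
  if (!any(memb == "low") || !any(memb == "high"))
    stop("a quartile group is empty after boundary ties")
  res <- groupCompare(decline[memb != "mid"],
                      factor(memb[memb != "mid"], levels = c("low", "high"),
                             labels = c("low_expr", "high_expr")),
                      familySize = familySize)
  attr(res, "membership") <- memb
  res
}

#' Project a reference module eigengene into an external cohort
#'
#' Z-scores the external matrix per gene and projects its samples onto the
#' reference module's first-singular-vector gene weights, restricted to
#' the genes shared with the external matrix and renormalized to unit
#' norm. At least half of the module's genes must be present.
#'
#' @param external genes x samples matrix or `SummarizedExperiment`.
#' @param moduleSet the reference [ModuleSet-class].
#' @param module module label (integer) or eigengene row name (`"M3"`).
#' @return Named numeric vector: the projected eigengene per external
#'   sample (unit norm). Missing module genes are reported via
#'   `message()`.
#' @export
projectEigengene <- function(external, moduleSet, module) {
  stopifnot(methods::is(moduleSet, "ModuleSet"))
  key <- if (is.numeric(module)) paste0("M", module) else module
  w <- moduleLoadings(moduleSet)[[key]]
  if (is.null(w)) stop("unknown module: ", key)
  m <- .exprsMatrix(external)
  shared <- intersect(names(w), rownames(m))
  frac <- length(shared) / length(w)
  if (frac < 0.5)
    stop("only ", length(shared), "/", length(w), " module genes present ",
         "in the external matrix (", round(100 * frac), "% < 50%)")
  if (length(shared) < length(w))
    message(length(w) - length(shared), " module gene(s) missing from the ",
            "external matrix; projecting on ", length(shared), " genes")
  sub <- m[shared, , drop = FALSE]
  z <- t(scale(t(sub)))
  ww <- w[shared] / sqrt(sum(w[shared]^2))
  proj <- as.vector(crossprod(z, ww))
  names(proj) <- colnames(m)
  nrm <- sqrt(sum(proj^2))
  if (nrm > 0) proj <- proj / nrm
  proj
}
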