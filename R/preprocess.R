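#' Z-score normalize expression per gene
#'
#' Centers and scales every gene row to mean 0 and sample standard deviation
#' 1 (denominator n - 1). This is the standardization applied to microarray
#' and bulk RNA-seq matrices before module construction, so that genes with
#' different baseline intensities become comparable.
#'
#' @param x genes x samples numeric matrix, or a `SummarizedExperiment`
#'   (first assay is used and replaced).
#' @param dropConstant if `TRUE`, zero-variance genes are removed with a
#'   message; if `FALSE` (default) a zero-variance gene is an error naming
#'   the gene.
#' @return An object of the same class as `x` with every row at mean 0 /
#'   sd 1 and attribute `normalized = TRUE` on the matrix.
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 5, 8), 2, 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' zscoreGenes(m)
#' @export
zscoreGenes <- function(x, dropConstant = FALSE) {
  m <- .exprsMatrix(x)
  if (anyNA(m)) stop("matrix contains missing values; resolve them on load")
  sds <- apply(m, 1L, stats::sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    bad <- rownames(m)[zero]
    if (is.null(bad)) bad <- which(zero)
    if (!dropConstant)
      stop("zero-variance gene(s): ", paste(utils::head(bad, 5L), collapse = ", "),
           if (sum(zero) > 5L) " ..." else "",
           " (set dropConstant = TRUE to remove)")
    message("dropping ", sum(zero), " zero-variance gene(s): ",
            paste(utils::head(bad, 5L), collapse = ", "))
    m <- m[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  z <- (m - rowMeans(m)) / sds
  attr(z, "normalized") <- TRUE
  if (methods::is(x, "SummarizedExperiment")) {
    if (any(zero)) x <- x[!zero, ]
    SummarizedExperiment::assay(x, 1L) <- z
    return(x)
  }
  z
}

#' Filter genes by expression variability
#'
#' Retains the most variable genes, the standard pre-filter before network
#' construction (the fraction defaults to the top quarter by standard
#' deviation). Either a fraction or an absolute count can be given; the
#' survivors keep their original row order, and ties at the threshold are
#' broken by input order.
#'
#' @param x genes x samples matrix or `SummarizedExperiment`.
#' @param keepFraction fraction of genes to keep, in (0, 1]; `ceiling(f * n)`
#'   rows are retained. Ignored when `keepCount` is given.
#' @param keepCount absolute number of genes to keep (overrides
#'   `keepFraction`).
#' @return Object of the same class as `x`, restricted to the retained rows.
#' @examples
#' m <- matrix(rnorm(80, sd = rep(1:8, 10)), 8, 10)
#' rownames(m) <- paste0("g", 1:8)
#' nrow(filterByVariance(m, keepFraction = 0.25))  # 2
#' @export
filterByVariance <- function(x, keepFraction = 0.25, keepCount = NULL) {
  m <- .exprsMatrix(x)
  n <- nrow(m)
  if (!is.null(keepCount)) {
    k <- as.integer(keepCount)
    if (is.na(k) || k < 1L || k > n)
      stop("keepCount must be an integer in [1, ", n, "]")
  } else {
    if (!is.numeric(keepFraction) || length(keepFraction) != 1L ||
        is.na(keepFraction) || keepFraction <= 0 || keepFraction > 1)
      stop("keepFraction must lie in (0, 1]")
    k <- as.integer(ceiling(keepFraction * n))
  }
  sds <- apply(m, 1L, stats::sd)
  # stable sort: ties at the cut are resolved by input order
  keep <- sort(order(sds, decreasing = TRUE)[seq_len(k)])
  if (methods::is(x, "SummarizedExperiment")) return(x[keep, ])
  m[keep, , drop = FALSE]
}

#' Classify samples into reserve / loss-reserve
#'
#' Cognitive reserve is the capacity to maintain cognition despite
#' accumulating pathology; it is operationalized as preserved MMSE in the
#' presence of at least moderate tangle spread. The rule: `reserve` when
#' MMSE > 26 and Braak >= 3; `loss_reserve` when MMSE < 26. Borderline
#' MMSE = 26 is resolved by `borderlinePolicy` (default: reserve iff
#' Braak >= 3, the only quantitative criterion available). Samples that are
#' cognitively intact without pathology (MMSE > 26, Braak < 3) are
#' `not_evaluable`: reserve is only meaningful when pathology is present,
#' and they are excluded from reserve contrasts.
#'
#' @param phenotypes data.frame (or `SummarizedExperiment` colData) with
#'   numeric columns `mmse` and `braak`.
#' @param mmseHigh MMSE threshold (default 26).
#' @param braakMin minimum Braak stage for reserve (default 3).
#' @param borderlinePolicy how to label MMSE exactly at `mmseHigh`:
#'   `"braak"` (reserve iff Braak >= `braakMin`, default), `"reserve"` or
#'   `"loss_reserve"`.
#' @return `phenotypes` with a `reserve_label` factor column
#'   (levels reserve, loss_reserve, not_evaluable); label counts are
#'   reported via `message()`.
#' @examples
#' ph <- data.frame(mmse = c(27, 20, 26, 26, 29), braak = c(3, 5, 4, 1, 0))
#' classifyReserve(ph)$reserve_label
#' @export
classifyReserve <- function(phenotypes, mmseHigh = 26, braakMin = 3,
                            borderlinePolicy = c("braak", "reserve",
                                                 "loss_reserve")) {
  borderlinePolicy <- match.arg(borderlinePolicy)
  ph <- .phenoTable(phenotypes)
  for (col in c("mmse", "braak"))
    if (is.null(ph[[col]]))
      stop("phenotype table lacks required column '", col, "'")
  miss <- is.na(ph$mmse) | is.na(ph$braak)
  if (any(miss))
    stop("missing mmse/braak for sample(s): ",
         paste(utils::head(which(miss), 10L), collapse = ", "))
  lab <- rep("not_evaluable", nrow(ph))
  lab[ph$mmse > mmseHigh & ph$braak >= braakMin] <- "reserve"
  lab[ph$mmse < mmseHigh] <- "loss_reserve"
  border <- ph$mmse == mmseHigh
  if (any(border)) {
    lab[border] <- switch(borderlinePolicy,
      braak = ifelse(ph$braak[border] >= braakMin, "reserve", "loss_reserve"),
      reserve = "reserve",
      loss_reserve = "loss_reserve")
  }
  ph$reserve_label <- factor(lab, levels = c("reserve", "loss_reserve",
                                             "not_evaluable"))
  counts <- table(ph$reserve_label)
  message("reserve labels: ",
          paste(names(counts), counts, sep = " = ", collapse = ", "))
  if (methods::is(phenotypes, "SummarizedExperiment")) {
    SummarizedExperiment::colData(phenotypes)$reserve_label <- ph$reserve_label
    return(phenotypes)
  }
  ph
}

#' Assign disease-severity groups from MMSE
#'
#' Bins samples into the four severity groups used for the cohort:
#' control (MMSE > 25), incipient (MMSE 20-25), moderate (MMSE 14-19) and
#' severe (MMSE < 14). Boundaries are inclusive as printed and assume
#' integer MMSE; a non-integer score falling into a gap between bins
#' (e.g. 19.5) is an error demanding an explicit rounding policy.
#'
#' @param phenotypes data.frame (or `SummarizedExperiment`) with column
#'   `mmse`.
#' @return `phenotypes` with a `diagnosis_group` factor column (levels
#'   control, incipient, moderate, severe).
#' @examples
#' severityGroups(data.frame(mmse = c(27, 25, 22, 15, 10)))$diagnosis_group
#' @export
severityGroups <- function(phenotypes) {
  ph <- .phenoTable(phenotypes)
  if (is.null(ph$mmse)) stop("phenotype table lacks required column 'mmse'")
  m <- ph$mmse
  if (anyNA(m)) stop("missing mmse for sample(s): ",
                     paste(which(is.na(m)), collapse = ", "))
  gap <- (m > 19 & m < 20) | (m > 13 & m < 14)
  if (any(gap))
    stop("non-integer MMSE between severity bins (",
         paste(m[gap], collapse = ", "),
         "): apply an explicit rounding policy first")
  grp <- ifelse(m > 25, "control",
         ifelse(m >= 20, "incipient",
         ifelse(m >= 14, "moderate", "severe")))
  ph$diagnosis_group <- factor(grp, levels = c("control", "incipient",
                                               "moderate", "severe"))
  if (methods::is(phenotypes, "SummarizedExperiment")) {
    SummarizedExperiment::colData(phenotypes)$diagnosis_group <-
      ph$diagnosis_group
    return(phenotypes)
  }
  ph
}
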