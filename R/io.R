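# TSV readers/writers for the pipeline's tabular formats and GraphML export
# for network interchange with graph viewers.

#' Read a genes x samples expression matrix from TSV
#'
#' Expects UTF-8 tab-separated text: header row of sample ids, first
#' column gene ids. Malformed headers, ragged rows and duplicate gene ids
#' raise descriptive errors with line numbers. Rows containing missing
#' cells are dropped with a message (set `naAction = "error"` to fail
#' instead).
#'
#' @param path file path.
#' @param naAction `"drop"` (default) or `"error"` for rows with missing
#'   values.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
readExpression <- function(path, naAction = c("drop", "error")) {
  naAction <- match.arg(naAction)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (length(header) < 2L)
    stop("malformed header (line 1): need a gene-id column plus at least ",
         "one sample column")
  samples <- header[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample id(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  nc <- length(header)
  widths <- lengths(cells[-1L])
  ragged <- which(widths != nc)
  if (length(ragged))
    stop("ragged row(s) at line(s) ",
         paste(utils::head(ragged + 1L, 5L), collapse = ", "),
         ": expected ", nc, " fields")
  genes <- vapply(cells[-1L], `[[`, character(1L), 1L)
  dup <- which(duplicated(genes))
  if (length(dup))
    stop("duplicated gene id '", genes[dup[1L]], "' at line ", dup[1L] + 1L)
  vals <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(cells[-1L], `[`, -1L)))),
    nrow = length(genes), byrow = TRUE,
    dimnames = list(genes, samples))
  bad <- which(apply(vals, 1L, anyNA))
  if (length(bad)) {
    if (naAction == "error")
      stop("missing/non-numeric values in row(s): ",
           paste(utils::head(genes[bad], 5L), collapse = ", "))
    message("dropping ", length(bad), " row(s) with missing values: ",
            paste(utils::head(genes[bad], 5L), collapse = ", "))
    vals <- vals[-bad, , drop = FALSE]
  }
  vals
}

#' Write a genes x samples expression matrix as TSV
#'
#' Full-precision output so that write -> read round trips are exact to
#' floating precision.
#'
#' @param x matrix or `SummarizedExperiment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  m <- .exprsMatrix(x)
  out <- cbind(gene_id = rownames(m),
               matrix(.fmtNum(m), nrow(m), ncol(m),
                      dimnames = list(NULL, colnames(m))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Requires columns `sample_id` (or rownames via first column), `mmse` and
#' `braak`; optional `nft`, `age`, `sex`, `pmi`, `diagnosis_group`,
#' `reserve_label`. Range checks: MMSE in \[0, 30\], Braak in \[0, 6\],
#' NFT >= 0. Sex strings (`M`, `F`, `male`, `female`, any case) are
#' normalized to `male` / `female`.
#'
#' @param path file path.
#' @return data.frame with sample ids as rownames and typed columns.
#' @export
readPhenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  idCol <- if ("sample_id" %in% names(ph)) "sample_id" else names(ph)[1L]
  rownames(ph) <- as.character(ph[[idCol]])
  ph[[idCol]] <- NULL
  for (col in c("mmse", "braak"))
    if (is.null(ph[[col]]))
      stop("phenotype file lacks required column '", col, "'")
  rangeCheck <- function(col, lo, hi) {
    v <- ph[[col]]
    if (is.null(v)) return()
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad))
      stop("out-of-range ", col, " for sample(s) ",
           paste(utils::head(rownames(ph)[bad], 5L), collapse = ", "),
           " (allowed [", lo, ", ", hi, "])")
  }
  for (col in intersect(c("mmse", "braak", "nft", "age", "pmi"), names(ph)))
    ph[[col]] <- as.numeric(ph[[col]])
  rangeCheck("mmse", 0, 30)
  rangeCheck("braak", 0, 6)
  rangeCheck("nft", 0, Inf)
  if (!is.null(ph$sex)) {
    s <- tolower(trimws(as.character(ph$sex)))
    norm <- ifelse(s %in% c("m", "male"), "male",
            ifelse(s %in% c("f", "female"), "female", NA_character_))
    if (anyNA(norm[!is.na(s)]))
      stop("unrecognized sex value(s): ",
           paste(unique(ph$sex[is.na(norm)]), collapse = ", "))
    ph$sex <- norm
  }
  ph
}

#' Write a phenotype table as TSV
#' @param phenotypes data.frame with sample rownames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(phenotypes, path) {
  ph <- .phenoTable(phenotypes)
  out <- cbind(sample_id = rownames(ph), ph)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network as a directed edge-list TSV
#'
#' Columns `from`, `to`, `frequency` (arc strength when available).
#'
#' @param fit a [BayesNetFit-class], an `igraph` graph, or a two-column
#'   arc matrix.
#' @param path output file path.
#' @param strengthOnly write the full arc-frequency table instead of the
#'   consensus arcs (default FALSE).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(fit, path, strengthOnly = FALSE) {
  df <- if (methods::is(fit, "BayesNetFit")) {
    if (strengthOnly) fit@strength
    else {
      a <- fit@arcs
      st <- fit@strength
      freq <- if (nrow(st))
        st$frequency[match(paste(a[, 1L], a[, 2L]),
                           paste(st$from, st$to))]
      else rep(NA_real_, nrow(a))
      data.frame(from = a[, 1L], to = a[, 2L], frequency = freq)
    }
  } else if (igraph::is_igraph(fit)) {
    el <- igraph::as_edgelist(fit)
    data.frame(from = el[, 1L], to = el[, 2L], frequency = NA_real_)
  } else {
    a <- .asArcMatrix(fit)
    data.frame(from = a[, 1L], to = a[, 2L], frequency = NA_real_)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' GraphML is the standard import format of graph viewers (e.g.
#' Cytoscape), so learned networks and hub subnetworks are exported this
#' way for visual inspection.
#'
#' @param net a [BayesNetFit-class] (converted to a directed `igraph`
#'   graph with edge attribute `frequency`) or an `igraph` graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNetworkGraphML <- function(net, path) {
  g <- if (methods::is(net, "BayesNetFit")) {
    gg <- igraph::make_empty_graph(n = length(net@nodes), directed = TRUE)
    gg <- igraph::set_vertex_attr(gg, "name", value = net@nodes)
    if (nrow(net@arcs)) {
      gg <- igraph::add_edges(gg, t(net@arcs))
      st <- net@strength
      freq <- st$frequency[match(paste(net@arcs[, 1L], net@arcs[, 2L]),
                                 paste(st$from, st$to))]
      gg <- igraph::set_edge_attr(gg, "frequency", value = freq)
    }
    gg
  } else net
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
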