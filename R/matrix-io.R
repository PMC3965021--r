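# Readers for gene x condition matrices, binary phyletic profiles and
# gene -> document citation indexes.

#' Read a gene-by-condition matrix from TSV
#'
#' Expects a header row of condition labels and a first column of gene
#' identifiers; empty cells or `NA` denote missing values. Gene identifiers
#' are uppercased; row and column labels must be unique.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames and condition colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- toupper(rownames(m))
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers in matrix", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate condition labels in matrix", call. = FALSE)
  m
}

#' @rdname read_expression
#' @param m Matrix with gene rownames and condition colnames.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binary phyletic profiles from TSV
#'
#' Same layout as [read_expression()] (genes in rows, reference genomes in
#' columns) but entries must be 0/1 presence calls and at least two genomes
#' are required.
#'
#' @param path Path to a TSV file.
#' @return Integer 0/1 matrix with gene rownames and genome colnames.
#' @export
read_profiles <- function(path) {
  m <- read_expression(path)
  if (ncol(m) < 2L) stop("phyletic profiles need >= 2 reference genomes", call. = FALSE)
  if (any(is.na(m)) || any(!m %in% c(0, 1))) {
    stop("phyletic profile entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Construct a citation index
#'
#' Maps each gene to the set of document identifiers citing it, against a
#' total corpus size used as the hypergeometric universe.
#'
#' @param docs_by_gene Named list: gene -> character vector of document ids.
#' @param corpus_size Total number of documents in the corpus; must be at
#'   least 1 and at least the number of distinct documents referenced.
#' @return A list of class `fl_citations`.
#' @export
citation_index <- function(docs_by_gene, corpus_size) {
  if (is.null(names(docs_by_gene)) || any(!nzchar(names(docs_by_gene)))) {
    stop("docs_by_gene must be a named list", call. = FALSE)
  }
  docs_by_gene <- lapply(docs_by_gene, function(d) unique(as.character(d)))
  names(docs_by_gene) <- toupper(names(docs_by_gene))
  corpus_size <- as.integer(corpus_size)
  if (corpus_size < 1L) stop("corpus_size must be >= 1", call. = FALSE)
  n_ref <- length(unique(unlist(docs_by_gene)))
  if (n_ref > corpus_size) {
    stop(sprintf("corpus_size (%d) smaller than referenced documents (%d)",
                 corpus_size, n_ref), call. = FALSE)
  }
  structure(list(docs_by_gene = docs_by_gene, corpus_size = corpus_size),
            class = "fl_citations")
}

#' Read a citation index from TSV
#'
#' Two columns, no header: gene identifier, document identifier; one row per
#' citation.
#'
#' @param path Path to a TSV file.
#' @param corpus_size Total corpus size (defaults to the number of distinct
#'   document ids in the file).
#' @return A [citation_index].
#' @export
read_citations <- function(path, corpus_size = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene", "doc"), colClasses = "character")
  if (is.null(corpus_size)) corpus_size <- length(unique(df$doc))
  citation_index(split(df$doc, df$gene), corpus_size)
}
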