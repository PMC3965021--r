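# Named gene-set collections (pathways, GO terms, phenotype sets, DEG lists).

#' Construct a gene-set collection
#'
#' A named list of nonempty gene-identifier sets with unique names, used for
#' pathway annotations, GO biological-process terms, phenotype gene sets and
#' hub-neighbor sets alike. Identifiers are uppercased and deduplicated.
#'
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled or named to match `sets`.
#' @return A list of class `fl_genesets`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!length(sets)) stop("gene-set collection must be nonempty", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  sets <- lapply(sets, function(g) sort(unique(toupper(as.character(g)))))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ", nm[lengths(sets) == 0L][1], call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  attr(sets, "descriptions") <- stats::setNames(as.character(descriptions), nm)
  class(sets) <- "fl_genesets"
  sets
}

#' @export
print.fl_genesets <- function(x, ...) {
  cat(sprintf("<fl_genesets: %d sets, %d distinct genes>\n",
              length(x), length(unique(unlist(x)))))
  for (nm in utils::head(names(x), 5L)) {
    cat(sprintf("  %s (%d genes)\n", nm, length(x[[nm]])))
  }
  if (length(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate member genes within a line are collapsed;
#' duplicate set names or lines with fewer than three fields are errors.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines_kept <- which(nzchar(lines))
  if (!length(lines_kept)) stop("GMT file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines[lines_kept], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("parse error at line %d of %s: GMT lines need >= 3 fields",
                 lines_kept[which(nf < 3L)[1]], path), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set name in GMT: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  gene_set_collection(stats::setNames(members, nm), descriptions = desc)
}

#' Write gene sets in GMT format
#' @param sets A [gene_set_collection].
#' @param path Output file path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "fl_genesets"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
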