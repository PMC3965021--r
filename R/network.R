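# Core containers: canonical gene pairs and weighted data-specific networks.

# Canonicalize pair endpoints: uppercase identifiers, lexicographically
# ordered so (x, y) and (y, x) denote the same undirected link.
canonical_pairs <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  list(a = a, b = b)
}

pair_key <- function(a, b) paste(a, b, sep = "\r")

#' Construct a data-specific functional network
#'
#' A `fl_network` is an undirected weighted edge list over gene identifiers:
#' one row per cofunctional link, with a data-type tag (e.g. `"CX"` for
#' co-expression, `"PG"` for phylogenetic profiles) recording the evidence
#' the weights were derived from. Pairs are stored canonically (uppercase,
#' lexicographically ordered endpoints), self-links are forbidden, and each
#' pair appears at most once.
#'
#' @param a,b Character vectors of gene identifiers (endpoints).
#' @param weight Numeric vector of finite link weights, typically
#'   log-likelihood scores in natural-log units.
#' @param tag Single string labelling the evidence type.
#' @return A data.frame of class `fl_network` with columns `a`, `b`,
#'   `weight` and a `tag` attribute.
#' @examples
#' net <- fl_network(c("yBR1", "YAL2"), c("YAL2", "YCR3"), c(1.5, 2), tag = "CX")
#' network_genes(net)
#' @export
fl_network <- function(a, b, weight = numeric(length(a)), tag = "untagged") {
  if (length(a) != length(b) || length(a) != length(weight)) {
    stop("a, b and weight must have equal length", call. = FALSE)
  }
  weight <- as.numeric(weight)
  if (length(weight) && any(!is.finite(weight))) {
    stop("network weights must be finite", call. = FALSE)
  }
  cp <- canonical_pairs(a, b)
  if (any(cp$a == cp$b)) {
    bad <- unique(cp$a[cp$a == cp$b])
    stop("self-links are not allowed: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  key <- pair_key(cp$a, cp$b)
  if (anyDuplicated(key)) {
    # identical duplicates collapse; conflicting weights are an error
    first <- match(key, key)
    conflict <- weight != weight[first]
    if (any(conflict)) {
      stop("duplicate pair with conflicting scores: ",
           sub("\r", "-", key[conflict][1]), call. = FALSE)
    }
    keep <- !duplicated(key)
    cp$a <- cp$a[keep]; cp$b <- cp$b[keep]; weight <- weight[keep]
  }
  out <- data.frame(a = cp$a, b = cp$b, weight = weight,
                    stringsAsFactors = FALSE)
  attr(out, "tag") <- as.character(tag)
  class(out) <- c("fl_network", "data.frame")
  out
}

#' @export
print.fl_network <- function(x, ...) {
  cat(sprintf("<fl_network tag=%s: %d genes, %d links>\n",
              network_tag(x), length(network_genes(x)), nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Genes covered by a network
#'
#' @param net A [fl_network].
#' @return Sorted character vector of distinct gene identifiers touched by
#'   at least one link.
#' @export
network_genes <- function(net) sort(unique(c(net$a, net$b)))

#' Evidence-type tag of a network
#' @param net A [fl_network].
#' @export
network_tag <- function(net) attr(net, "tag") %||% "untagged"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a network edge list from TSV
#'
#' Reads the 3-column tab-separated dialect used for network downloads:
#' `geneA<TAB>geneB<TAB>score`, no header by default. Pairs are
#' canonicalized on read; self-links, malformed lines and duplicate pairs
#' carrying conflicting scores are rejected with the offending line number.
#'
#' @param path Path to a TSV file.
#' @param tag Evidence-type tag to attach (default: file name sans extension).
#' @param header Set `TRUE` if the file carries a header row to skip.
#' @return A [fl_network].
#' @export
read_edge_list <- function(path, tag = NULL, header = FALSE) {
  if (is.null(tag)) tag <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1L]
  lines_kept <- which(nzchar(lines))
  if (!length(lines_kept)) return(fl_network(character(), character(), numeric(), tag = tag))
  fields <- strsplit(lines[lines_kept], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    ln <- lines_kept[which(nf != 3L)[1]] + if (header) 1L else 0L
    stop(sprintf("parse error at line %d of %s: expected 3 tab-separated fields, found %d",
                 ln, path, nf[nf != 3L][1]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  score <- suppressWarnings(as.numeric(m[, 3L]))
  if (any(!is.finite(score))) {
    ln <- lines_kept[which(!is.finite(score))[1]] + if (header) 1L else 0L
    stop(sprintf("parse error at line %d of %s: score '%s' is not a finite number",
                 ln, path, m[!is.finite(score), 3L][1]), call. = FALSE)
  }
  fl_network(m[, 1L], m[, 2L], score, tag = tag)
}

#' Write a network edge list to TSV
#'
#' Rows are emitted sorted by descending weight, ties broken by canonical
#' pair order, so output is deterministic and `read_edge_list()` round-trips
#' exactly. An empty network yields an empty file.
#'
#' @param net A [fl_network].
#' @param path Output file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "fl_network"))
  o <- order(-net$weight, net$a, net$b)
  lines <- if (nrow(net)) {
    sprintf("%s\t%s\t%.15g", net$a[o], net$b[o], net$weight[o])
  } else character()
  writeLines(lines, path)
  invisible(path)
}

# Named weight lookup for a set of pairs; NA where the pair is absent.
network_weight <- function(net, a, b) {
  cp <- canonical_pairs(a, b)
  net$weight[match(pair_key(cp$a, cp$b), pair_key(net$a, net$b))]
}
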