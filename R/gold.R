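# Pathway-derived gold standards: positive pairs share >= 1 annotation set,
# negative pairs are annotated genes that never share one.

#' Construct a gold standard of positive and negative gene pairs
#'
#' @param positives,negatives Two-column data.frames (or lists with elements
#'   `a`, `b`) of gene pairs. Pairs are canonicalized; the two sets must be
#'   disjoint and free of self-links.
#' @return A list of class `fl_gold` with data.frame elements `positives`
#'   and `negatives`.
#' @export
gold_standard <- function(positives, negatives) {
  canon <- function(df) {
    cp <- canonical_pairs(df$a, df$b)
    if (any(cp$a == cp$b)) stop("gold standard contains a self-link", call. = FALSE)
    keep <- !duplicated(pair_key(cp$a, cp$b))
    data.frame(a = cp$a[keep], b = cp$b[keep], stringsAsFactors = FALSE)
  }
  pos <- canon(as.data.frame(positives))
  neg <- canon(as.data.frame(negatives))
  if (length(intersect(pair_key(pos$a, pos$b), pair_key(neg$a, neg$b)))) {
    stop("gold positives and negatives overlap", call. = FALSE)
  }
  structure(list(positives = pos, negatives = neg), class = "fl_gold")
}

#' @export
print.fl_gold <- function(x, ...) {
  cat(sprintf("<fl_gold: %d positive, %d negative pairs>\n",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

all_pairs <- function(genes) {
  genes <- sort(unique(genes))
  n <- length(genes)
  if (n < 2L) return(data.frame(a = character(), b = character()))
  idx <- utils::combn(n, 2L)
  data.frame(a = genes[idx[1L, ]], b = genes[idx[2L, ]], stringsAsFactors = FALSE)
}

#' Derive a gold standard from pathway annotations
#'
#' Positives are all distinct gene pairs co-annotated to at least one set;
#' negatives are pairs in which both genes carry some annotation but never
#' share a set. This is the usual reading of pathway-derived benchmarks:
#' a pair is only called negative when both genes are known well enough to
#' be annotated somewhere.
#'
#' @param pathways A [gene_set_collection] of pathway annotations.
#' @return A [gold_standard].
#' @examples
#' paths <- gene_set_collection(list(S1 = c("A", "B", "C"), S2 = c("C", "D")))
#' gold_from_annotations(paths)
#' @export
gold_from_annotations <- function(pathways) {
  stopifnot(inherits(pathways, "fl_genesets"))
  annotated <- unique(unlist(pathways))
  if (length(annotated) < 2L) {
    stop("need at least 2 annotated genes to form gold pairs", call. = FALSE)
  }
  pos_list <- lapply(pathways, all_pairs)
  pos <- do.call(rbind, pos_list)
  pos <- pos[!duplicated(pair_key(pos$a, pos$b)), , drop = FALSE]
  univ <- all_pairs(annotated)
  neg <- univ[!(pair_key(univ$a, univ$b) %in% pair_key(pos$a, pos$b)), , drop = FALSE]
  gold_standard(pos, neg)
}

#' Overlap between gold-standard positives and a network
#'
#' Counts gold positive pairs that are present as network links, reporting
#' the raw count together with two fractions whose denominators are both
#' defensible: all gold positives, and gold positives restricted to pairs
#' whose genes both occur in the network (the network-evaluable positives).
#'
#' @param gold A [gold_standard].
#' @param net A [fl_network].
#' @return A list with `count`, `fraction_of_positives` and
#'   `fraction_of_evaluable_positives`.
#' @export
overlap_fraction <- function(gold, net) {
  stopifnot(inherits(gold, "fl_gold"), inherits(net, "fl_network"))
  if (!nrow(gold$positives) || !nrow(net)) {
    stop("gold standard and network must both be nonempty", call. = FALSE)
  }
  pos_key <- pair_key(gold$positives$a, gold$positives$b)
  net_key <- pair_key(net$a, net$b)
  count <- sum(pos_key %in% net_key)
  genes <- network_genes(net)
  evaluable <- sum(gold$positives$a %in% genes & gold$positives$b %in% genes)
  list(count = count,
       fraction_of_positives = count / length(pos_key),
       fraction_of_evaluable_positives = if (evaluable) count / evaluable else NA_real_)
}

#' Write / read a gold standard as TSV
#'
#' Three columns: geneA, geneB, label (`1` positive, `0` negative).
#' @param gold A [gold_standard].
#' @param path File path.
#' @export
write_gold <- function(gold, path) {
  df <- rbind(cbind(gold$positives, label = 1L), cbind(gold$negatives, label = 0L))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gold
#' @export
read_gold <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("a", "b", "label"),
                          colClasses = c("character", "character", "integer"))
  gold_standard(df[df$label == 1L, c("a", "b")], df[df$label == 0L, c("a", "b")])
}
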