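# Raw-evidence scorers: turn primary data into ranked gene-pair evidence
# tables, the substrate that rank-binned LLS calibration operates on.

#' Construct an evidence table
#'
#' A table of canonical gene pairs with finite raw evidence scores on an
#' arbitrary, data-type-specific scale (Pearson r, mutual information,
#' -log10 p, ...). Raw scores are only ever used through their ranking, so
#' scorers for further data types can be supplied externally as TSV and read
#' with [read_evidence()].
#'
#' @param a,b Character vectors of gene identifiers.
#' @param raw_score Finite numeric scores, higher = stronger evidence.
#' @param tag Evidence-type tag.
#' @return A data.frame of class `fl_evidence` with columns `a`, `b`,
#'   `raw_score` and a `tag` attribute.
#' @export
evidence_table <- function(a, b, raw_score, tag = "untagged") {
  if (length(raw_score) && any(!is.finite(raw_score))) {
    stop("raw scores must be finite", call. = FALSE)
  }
  cp <- canonical_pairs(a, b)
  if (any(cp$a == cp$b)) stop("self-pairs are not allowed in evidence", call. = FALSE)
  if (anyDuplicated(pair_key(cp$a, cp$b))) {
    stop("duplicate pair in evidence table", call. = FALSE)
  }
  out <- data.frame(a = cp$a, b = cp$b, raw_score = as.numeric(raw_score),
                    stringsAsFactors = FALSE)
  attr(out, "tag") <- as.character(tag)
  class(out) <- c("fl_evidence", "data.frame")
  out
}

#' @export
print.fl_evidence <- function(x, ...) {
  cat(sprintf("<fl_evidence tag=%s: %d scored pairs>\n",
              attr(x, "tag"), nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x[order(-x$raw_score), ]), 6L))
  invisible(x)
}

#' Read / write evidence tables as 3-column TSV
#' @param path File path.
#' @param tag Evidence-type tag (default: file name sans extension).
#' @export
read_evidence <- function(path, tag = NULL) {
  net <- read_edge_list(path, tag = tag)
  evidence_table(net$a, net$b, net$weight, tag = network_tag(net))
}

#' @rdname read_evidence
#' @param ev An [evidence_table].
#' @export
write_evidence <- function(ev, path) {
  o <- order(-ev$raw_score, ev$a, ev$b)
  writeLines(sprintf("%s\t%s\t%.15g", ev$a[o], ev$b[o], ev$raw_score[o]), path)
  invisible(path)
}

# row/col indices of the upper triangle of an n x n matrix
upper_idx <- function(n) {
  ut <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  list(i = ut[, 1L], j = ut[, 2L])
}

#' Co-expression evidence: pairwise Pearson correlation
#'
#' Scores every gene pair by the Pearson correlation of their expression
#' profiles over the conditions where both are observed (complete-pairs
#' handling of missing values). Pairs with fewer than `min_pairs` complete
#' observations, and pairs where either profile has zero variance over the
#' shared conditions, are omitted (the latter with a message, since the
#' correlation is undefined there).
#'
#' @param expr Numeric gene-by-condition matrix (see [read_expression()]);
#'   needs >= 3 conditions.
#' @param min_pairs Minimum complete observations per pair (default 10,
#'   >= 3).
#' @return An [evidence_table] with tag `"CX"`, scores in \[-1, 1\].
#' @export
coexpression_scores <- function(expr, min_pairs = 10L) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3L, min_pairs >= 3L)
  genes <- toupper(rownames(expr))
  n <- nrow(expr)
  if (n < 2L) stop("need >= 2 genes", call. = FALSE)
  tx <- t(expr)
  r <- suppressWarnings(stats::cor(tx, use = "pairwise.complete.obs"))
  n_obs <- crossprod(!is.na(tx))
  ut <- upper_idx(n)
  rv <- r[cbind(ut$i, ut$j)]
  enough <- n_obs[cbind(ut$i, ut$j)] >= min_pairs
  undefined <- is.na(rv) & enough
  if (any(undefined)) {
    message(sum(undefined),
            " pair(s) omitted: zero variance over complete observations")
  }
  keep <- enough & !is.na(rv)
  evidence_table(genes[ut$i][keep], genes[ut$j][keep],
                 pmin(pmax(rv[keep], -1), 1), tag = "CX")
}

#' Phylogenetic-profile evidence: mutual information
#'
#' Scores every gene pair by the plug-in mutual information (in bits)
#' between their binary presence/absence vectors across reference genomes,
#' estimated from the 2x2 joint count table. No bias correction is applied;
#' at the genome counts this method is used with, plug-in bias is small
#' relative to the rank resolution calibration needs. Constant profiles
#' (a gene present in all or no genomes) yield 0 for every pair they enter,
#' reported with a message.
#'
#' @param profiles 0/1 gene-by-genome matrix (see [read_profiles()]);
#'   needs >= 2 genomes.
#' @return An [evidence_table] with tag `"PG"`, scores >= 0.
#' @export
phyletic_scores <- function(profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2L)
  if (any(!profiles %in% c(0L, 1L))) stop("profiles must be binary", call. = FALSE)
  genes <- toupper(rownames(profiles))
  n <- nrow(profiles)
  if (n < 2L) stop("need >= 2 genes", call. = FALSE)
  m <- ncol(profiles)
  X <- profiles * 1.0
  ones <- rowSums(X)
  constant <- ones == 0 | ones == m
  if (any(constant)) {
    message(sum(constant), " constant profile(s): their pairs score 0")
  }
  n11 <- tcrossprod(X)
  ut <- upper_idx(n)
  c11 <- n11[cbind(ut$i, ut$j)]
  c10 <- ones[ut$i] - c11
  c01 <- ones[ut$j] - c11
  c00 <- m - c11 - c10 - c01
  plogp <- function(cnt, pi, pj) {
    p <- cnt / m
    term <- p * log2(p / (pi * pj))
    ifelse(cnt == 0, 0, term)
  }
  pi1 <- ones[ut$i] / m; pj1 <- ones[ut$j] / m
  mi <- plogp(c11, pi1, pj1) + plogp(c10, pi1, 1 - pj1) +
        plogp(c01, 1 - pi1, pj1) + plogp(c00, 1 - pi1, 1 - pj1)
  mi <- pmax(mi, 0)  # clamp tiny negative rounding
  evidence_table(genes[ut$i], genes[ut$j], mi, tag = "PG")
}

#' Co-citation evidence: hypergeometric enrichment of shared documents
#'
#' Scores each pair of genes sharing at least one citing document by
#' `-log10` of the one-sided hypergeometric probability of observing at
#' least the shared document count, given each gene's citation count and the
#' corpus size. Pairs sharing no documents are omitted. The hypergeometric
#' upper tail (rather than pointwise mutual information) keeps the score
#' directly comparable with the modulator-search statistic.
#'
#' @param index A [citation_index].
#' @return An [evidence_table] with tag `"CC"`, scores >= 0.
#' @export
cocitation_scores <- function(index) {
  stopifnot(inherits(index, "fl_citations"))
  genes <- names(index$docs_by_gene)
  N <- index$corpus_size
  counts <- lengths(index$docs_by_gene)
  if (any(counts > N)) {
    stop("a gene cites more documents than the corpus contains", call. = FALSE)
  }
  docs <- unique(unlist(index$docs_by_gene))
  inc <- matrix(0, nrow = length(genes), ncol = length(docs),
                dimnames = list(genes, docs))
  for (g in genes) inc[g, index$docs_by_gene[[g]]] <- 1
  shared <- tcrossprod(inc)
  ut <- upper_idx(length(genes))
  k <- shared[cbind(ut$i, ut$j)]
  keep <- k > 0
  if (!any(keep)) return(evidence_table(character(), character(), numeric(), tag = "CC"))
  p <- stats::phyper(k[keep] - 1, counts[ut$i][keep],
                     N - counts[ut$i][keep], counts[ut$j][keep],
                     lower.tail = FALSE)
  evidence_table(genes[ut$i][keep], genes[ut$j][keep], -log10(p), tag = "CC")
}
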