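# Network-guided hypothesis generation: candidate pathway members,
# neighbor-based function inference, and DEG-driven modulator search.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` marked items when `n` items are drawn without replacement from
#' a universe of `N` containing `K` marked ones. Computed through the
#' log-space distribution function, so extreme tails do not underflow.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Marked items (gene-set size).
#' @param n Draws (query size).
#' @param N Universe size; `K <= N`, `n <= N`.
#' @return Tail probability in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(K > N) || any(n > N)) {
    stop("hypergeometric parameters out of order: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Predict new members of a pathway or functional concept
#'
#' Guilt-by-association candidate ranking: every non-query network gene is
#' scored by the summed weight of its links to the query genes, using the
#' same scoring contract as [loo_gba_scores()], and the top candidates are
#' returned. Query members themselves are excluded from the output.
#'
#' @param net A [fl_network].
#' @param query Character vector of known member genes; at least one must
#'   be in the network.
#' @param top Number of candidates to return (default 30).
#' @return data.frame of `gene`, `score`, sorted by descending score with
#'   canonical name tie-break.
#' @export
find_new_members <- function(net, query, top = 30L) {
  stopifnot(inherits(net, "fl_network"))
  query <- unique(toupper(as.character(query)))
  genes <- network_genes(net)
  matched <- intersect(query, genes)
  if (!length(matched)) {
    stop("no query gene found in the network; unmatched: ",
         paste(query, collapse = ", "), call. = FALSE)
  }
  score <- stats::setNames(numeric(length(genes)), genes)
  hit_b <- net$b %in% matched
  hit_a <- net$a %in% matched
  if (any(hit_b)) {
    s <- tapply(net$weight[hit_b], net$a[hit_b], sum)
    score[names(s)] <- score[names(s)] + s
  }
  if (any(hit_a)) {
    s <- tapply(net$weight[hit_a], net$b[hit_a], sum)
    score[names(s)] <- score[names(s)] + s
  }
  cand <- setdiff(genes, matched)
  o <- cand[order(-score[cand], cand)]
  utils::head(data.frame(gene = o, score = unname(score[o]),
                         stringsAsFactors = FALSE), top)
}

#' Hub-neighbor gene sets
#'
#' One gene set per network gene, named after that central hub gene and
#' containing its direct network neighbors — plus the hub itself by default.
#' These are the predefined sets the modulator search tests a DEG query
#' against.
#'
#' @param net A nonempty [fl_network].
#' @param include_hub Include the hub in its own set (default `TRUE`).
#' @return A [gene_set_collection], one set per network gene.
#' @export
neighbor_sets <- function(net, include_hub = TRUE) {
  stopifnot(inherits(net, "fl_network"))
  if (!nrow(net)) stop("network is empty", call. = FALSE)
  nb <- c(split(net$b, net$a), split(net$a, net$b))
  nb <- lapply(split(nb, names(nb)), function(x) unique(unlist(x, use.names = FALSE)))
  if (include_hub) nb <- Map(c, names(nb), nb)
  gene_set_collection(nb)
}

#' Find candidate modulators for a cell state
#'
#' Given a set of differentially expressed genes (DEGs) for a cell-state
#' transition, tests every hub-neighbor set for enrichment of the DEGs by
#' the hypergeometric upper tail; a significantly associated set nominates
#' its central hub as a candidate modulator. Because association is through
#' network links, a hub can rank highly without itself being a DEG — the
#' point of the tool, since many genuine modulators show no transcriptional
#' response.
#'
#' By default the universe is the set of network genes and the draw count
#' is the number of DEGs among them. Supplying `universe_size` (e.g. a
#' genome-wide gene count, at least the network's gene count) switches to a
#' larger universe in which all DEGs are assumed to lie.
#'
#' @param net A [fl_network].
#' @param degs Character vector of DEGs; at least one must be in the
#'   network.
#' @param universe_size Optional universe size overriding the network-gene
#'   universe.
#' @param include_hub Passed to [neighbor_sets()].
#' @return data.frame of `hub`, `set_size`, `overlap`, `p_value`,
#'   `adjusted_p` (Benjamini–Hochberg, reported but not used for ranking),
#'   `rank`, sorted by ascending p, ties by descending overlap then hub
#'   name.
#' @export
find_modulators <- function(net, degs, universe_size = NULL, include_hub = TRUE) {
  degs <- unique(toupper(as.character(degs)))
  genes <- network_genes(net)
  degs_in_net <- intersect(degs, genes)
  if (!length(degs_in_net)) {
    stop("no DEG found in the network", call. = FALSE)
  }
  if (is.null(universe_size)) {
    N <- length(genes)
    n <- length(degs_in_net)
    degs_use <- degs_in_net
  } else {
    N <- as.integer(universe_size)
    if (N < length(genes)) {
      stop("universe_size smaller than the network's gene count", call. = FALSE)
    }
    n <- length(degs)
    degs_use <- degs
  }
  sets <- neighbor_sets(net, include_hub = include_hub)
  K <- lengths(sets)
  k <- vapply(sets, function(s) sum(s %in% degs_use), 0L)
  p <- hypergeom_tail(k, K, n, N)
  out <- data.frame(hub = names(sets), set_size = unname(K),
                    overlap = unname(k), p_value = unname(p),
                    adjusted_p = unname(stats::p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$overlap, out$hub), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Infer functions for a gene from its network neighbors
#'
#' Looks up the query gene's direct neighbors, and for every annotation
#' term hit by at least one neighbor computes the hypergeometric upper-tail
#' enrichment of the neighbors in that term. The universe is the annotated
#' network genes (configurable in spirit by pre-filtering `annotations`).
#' Terms are ranked by raw p-value and the `top` most enriched are
#' returned — 30 by default, the conventional listing size — with
#' Benjamini–Hochberg adjusted values reported alongside.
#'
#' @param net A [fl_network].
#' @param gene Query gene; must be in the network with >= 1 neighbor.
#' @param annotations A [gene_set_collection] of annotation terms (e.g.
#'   GO biological-process terms).
#' @param top Number of rows to return (default 30).
#' @return data.frame of `term`, `neighbor_hits`, `term_size`, `p_value`,
#'   `adjusted_p`, sorted by ascending p-value (ties by term name).
#' @export
infer_functions <- function(net, gene, annotations, top = 30L) {
  stopifnot(inherits(annotations, "fl_genesets"))
  gene <- toupper(gene)
  genes <- network_genes(net)
  if (!gene %in% genes) stop("query gene '", gene, "' not in network", call. = FALSE)
  neighbors <- unique(c(net$b[net$a == gene], net$a[net$b == gene]))
  if (!length(neighbors)) stop("query gene '", gene, "' is isolated", call. = FALSE)
  annotated <- intersect(genes, unique(unlist(annotations)))
  N <- length(annotated)
  n <- sum(neighbors %in% annotated)
  if (N == 0L || n == 0L) {
    stop("no annotated network gene among the neighbors", call. = FALSE)
  }
  rows <- lapply(names(annotations), function(term) {
    members <- intersect(annotations[[term]], annotated)
    k <- sum(neighbors %in% members)
    if (k < 1L) return(NULL)
    data.frame(term = term, neighbor_hits = k, term_size = length(members),
               p_value = hypergeom_tail(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top)
}
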