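# Rank-binned benchmarking: calibrate raw evidence scores into
# log-likelihood scores (LLS) against a gold standard.

#' Log-likelihood score of a bin
#'
#' The LLS of a set of gene pairs containing `p` gold positives and `n`
#' gold negatives, against prior totals `P` positives and `N` negatives,
#' is the natural-log odds ratio
#' \deqn{LLS = \ln\frac{(p+c)/(n+c)}{P/N}}
#' with a symmetric pseudocount `c` keeping zero cells finite. An LLS of 0
#' means the bin's odds equal the prior odds (the evidence is uninformative
#' at that rank); positive values mean enrichment for cofunctional pairs.
#'
#' @param p,n Positive / negative counts in the bin (`p + n > 0` unless a
#'   pseudocount is supplied).
#' @param P,N Prior totals over the whole gold standard; both > 0.
#' @param pseudocount Nonnegative smoothing constant added to `p` and `n`
#'   (default 0.5).
#' @return The LLS in natural-log units.
#' @examples
#' lls(5, 5, 10, 90, pseudocount = 0)  # log(9)
#' @export
lls <- function(p, n, P, N, pseudocount = 0.5) {
  stopifnot(P > 0, N > 0, pseudocount >= 0)
  if (any(p + n + pseudocount == 0)) {
    stop("LLS undefined: empty bin with zero pseudocount", call. = FALSE)
  }
  log(((p + pseudocount) / (n + pseudocount)) / (P / N))
}

#' Calibrate raw evidence scores to LLS by rank-binned benchmarking
#'
#' Gold-evaluable pairs (those in the gold standard's positives or
#' negatives) are sorted by descending raw score, ties broken by canonical
#' pair order, and partitioned into consecutive disjoint bins of `bin_size`
#' pairs. Each bin's LLS is computed with [lls()], then monotone
#' non-increasing LLS across bins is enforced by pooling adjacent violators:
#' whenever a later bin's LLS exceeds an earlier one's, the bins are merged
#' and the pooled LLS recomputed from the summed positive/negative counts,
#' so total counts are preserved exactly.
#'
#' @param ev An [evidence_table].
#' @param gold A [gold_standard].
#' @param bin_size Gold-evaluable pairs per bin (>= 2; 1000 is the
#'   conventional full-genome choice, smaller values suit toy data).
#' @param pseudocount Zero-cell smoothing for [lls()] (default 0.5).
#' @return A list of class `fl_calibration`: `bins` (per-bin statistics
#'   before pooling, with both raw and smoothed LLS), `knots` (the pooled
#'   monotone raw-score -> LLS map), `P`, `N`, `bin_size`, `pseudocount`,
#'   `tag`.
#' @export
calibrate <- function(ev, gold, bin_size = 1000L, pseudocount = 0.5) {
  stopifnot(inherits(ev, "fl_evidence"), inherits(gold, "fl_gold"),
            bin_size >= 2L)
  if (!nrow(ev)) stop("evidence table is empty", call. = FALSE)
  key <- pair_key(ev$a, ev$b)
  pos_key <- pair_key(gold$positives$a, gold$positives$b)
  neg_key <- pair_key(gold$negatives$a, gold$negatives$b)
  P <- length(pos_key); N <- length(neg_key)
  if (P == 0L || N == 0L) {
    stop("gold standard must contain both positives and negatives", call. = FALSE)
  }
  is_pos <- key %in% pos_key
  is_neg <- key %in% neg_key
  evaluable <- which(is_pos | is_neg)
  if (!length(evaluable)) {
    stop("no gold-evaluable pairs in evidence table", call. = FALSE)
  }
  o <- evaluable[order(-ev$raw_score[evaluable], ev$a[evaluable], ev$b[evaluable])]
  bin <- ceiling(seq_along(o) / bin_size)
  bins <- data.frame(
    bin_index = seq_len(max(bin)),
    pair_count = as.vector(table(bin)),
    pos = as.vector(tapply(is_pos[o], bin, sum)),
    neg = as.vector(tapply(is_neg[o], bin, sum)),
    mean_raw = as.vector(tapply(ev$raw_score[o], bin, mean))
  )
  bins$lls_raw <- lls(bins$pos, bins$neg, P, N, pseudocount)

  # pool-adjacent-violators on bin LLS: enforce non-increasing values by
  # merging counts, so pooled LLS is the LLS of the merged contingency
  pool <- list()
  for (i in seq_len(nrow(bins))) {
    blk <- list(pos = bins$pos[i], neg = bins$neg[i],
                count = bins$pair_count[i],
                raw_sum = bins$mean_raw[i] * bins$pair_count[i],
                members = i)
    pool[[length(pool) + 1L]] <- blk
    repeat {
      k <- length(pool)
      if (k < 2L) break
      v_last <- lls(pool[[k]]$pos, pool[[k]]$neg, P, N, pseudocount)
      v_prev <- lls(pool[[k - 1L]]$pos, pool[[k - 1L]]$neg, P, N, pseudocount)
      if (v_last <= v_prev) break
      merged <- list(pos = pool[[k - 1L]]$pos + pool[[k]]$pos,
                     neg = pool[[k - 1L]]$neg + pool[[k]]$neg,
                     count = pool[[k - 1L]]$count + pool[[k]]$count,
                     raw_sum = pool[[k - 1L]]$raw_sum + pool[[k]]$raw_sum,
                     members = c(pool[[k - 1L]]$members, pool[[k]]$members))
      pool[[k - 1L]] <- merged
      pool[[k]] <- NULL
    }
  }
  knots <- data.frame(
    mean_raw = vapply(pool, function(b) b$raw_sum / b$count, 0),
    lls = vapply(pool, function(b) lls(b$pos, b$neg, P, N, pseudocount), 0),
    pair_count = vapply(pool, function(b) b$count, 0)
  )
  bins$lls <- NA_real_
  for (b in pool) {
    bins$lls[b$members] <- lls(b$pos, b$neg, P, N, pseudocount)
  }
  structure(list(bins = bins, knots = knots, P = P, N = N,
                 bin_size = as.integer(bin_size), pseudocount = pseudocount,
                 tag = attr(ev, "tag")),
            class = "fl_calibration")
}

#' @export
print.fl_calibration <- function(x, ...) {
  cat(sprintf("<fl_calibration tag=%s: %d bins (%d after pooling), P=%d N=%d>\n",
              x$tag, nrow(x$bins), nrow(x$knots), x$P, x$N))
  print(utils::head(x$bins, 6L))
  invisible(x)
}

#' Map an evidence table through a fitted calibration
#'
#' Every pair — gold-evaluable or not — receives the LLS of its raw score
#' under the monotone map, interpolating linearly on mean raw score between
#' pooled-bin midpoints; scores above the first knot take the first bin's
#' LLS, scores below the last knot the last bin's. Pairs whose LLS is <= 0
#' carry no evidence beyond the prior and are dropped from the network.
#'
#' @param model An `fl_calibration` from [calibrate()].
#' @param ev An [evidence_table] (typically the one the model was fitted
#'   on, so that unevaluable pairs inherit LLS through their raw scores).
#' @return A [fl_network] of the pairs with LLS > 0, tagged like `ev`.
#' @export
apply_calibration <- function(model, ev) {
  stopifnot(inherits(model, "fl_calibration"), inherits(ev, "fl_evidence"))
  if (!nrow(ev)) {
    return(fl_network(character(), character(), numeric(), tag = attr(ev, "tag")))
  }
  kn <- model$knots
  # knots ordered by descending mean_raw; collapse exact raw-score ties
  if (anyDuplicated(kn$mean_raw)) {
    kn <- do.call(rbind, lapply(split(kn, kn$mean_raw), function(d) {
      data.frame(mean_raw = d$mean_raw[1],
                 lls = sum(d$lls * d$pair_count) / sum(d$pair_count),
                 pair_count = sum(d$pair_count))
    }))
  }
  kn <- kn[order(kn$mean_raw), , drop = FALSE]
  score <- if (nrow(kn) == 1L) {
    rep(kn$lls, nrow(ev))
  } else {
    stats::approx(kn$mean_raw, kn$lls, xout = ev$raw_score, rule = 2)$y
  }
  keep <- score > 0
  fl_network(ev$a[keep], ev$b[keep], score[keep], tag = attr(ev, "tag"))
}

#' Serialize / restore a calibration model
#'
#' Written as a YAML header (`P`, `N`, `bin_size`, `pseudocount`, `tag`)
#' followed by a TSV of per-bin statistics, all in one file.
#'
#' @param model An `fl_calibration`.
#' @param path File path.
#' @export
write_calibration <- function(model, path) {
  hdr <- yaml::as.yaml(model[c("P", "N", "bin_size", "pseudocount", "tag")])
  con <- textConnection("tsv", "w", local = TRUE)
  utils::write.table(model$bins, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  writeLines(c("---", sub("\n$", "", hdr), "---", tsv), path)
  invisible(path)
}
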