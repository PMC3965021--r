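# Network assessment: cumulative binned precision-recall, leave-one-out
# guilt-by-association ROC/AUC, extreme-tail phenotype sets, and paired
# network comparison by Wilcoxon signed-rank.

#' Cumulative binned precision-recall curve
#'
#' Network links are ranked by descending weight (ties by canonical pair
#' order) and walked cumulatively; after every `bin_size` links, and at the
#' end, a point is recorded with
#' precision = gold positives so far / gold-evaluable links so far, and
#' recall = distinct genes touched by any link so far / `genome_size`
#' (recall as genome coverage). Links not in the gold standard advance
#' recall but never the precision denominator, so precision reflects only
#' pairs the gold standard can adjudicate. Points before the first
#' gold-evaluable link carry `NA` precision.
#'
#' @param net A [fl_network].
#' @param gold A [gold_standard].
#' @param bin_size Links per cumulative bin (>= 1; 1000 conventionally).
#' @param genome_size Number of coding genes defining full recall; must be
#'   at least the network's gene count (5887 is the usual yeast figure, but
#'   it is deliberately an explicit argument).
#' @return A data.frame of class `fl_prcurve` with columns
#'   `pairs_considered`, `precision`, `recall`, plus a `genome_size`
#'   attribute.
#' @export
pr_curve <- function(net, gold, bin_size = 1000L, genome_size) {
  stopifnot(inherits(net, "fl_network"), inherits(gold, "fl_gold"),
            bin_size >= 1L)
  if (!nrow(net)) stop("network is empty", call. = FALSE)
  genes <- network_genes(net)
  if (genome_size < length(genes)) {
    stop("genome_size smaller than the network's gene count", call. = FALSE)
  }
  o <- order(-net$weight, net$a, net$b)
  a <- net$a[o]; b <- net$b[o]
  key <- pair_key(a, b)
  is_pos <- key %in% pair_key(gold$positives$a, gold$positives$b)
  is_neg <- key %in% pair_key(gold$negatives$a, gold$negatives$b)
  if (!any(is_pos | is_neg)) stop("no gold-evaluable links in network", call. = FALSE)
  cum_pos <- cumsum(is_pos)
  cum_eval <- cumsum(is_pos | is_neg)
  interleaved <- as.vector(rbind(a, b))
  cum_genes <- cumsum(!duplicated(interleaved))[seq(2L, 2L * length(a), by = 2L)]
  at <- unique(c(seq_len(length(a) %/% bin_size) * bin_size, length(a)))
  out <- data.frame(
    pairs_considered = at,
    precision = ifelse(cum_eval[at] > 0, cum_pos[at] / cum_eval[at], NA_real_),
    recall = cum_genes[at] / genome_size
  )
  attr(out, "genome_size") <- genome_size
  class(out) <- c("fl_prcurve", "data.frame")
  out
}

#' Area under a cumulative precision-recall curve
#'
#' Trapezoidal area over the curve's own (recall, precision) points,
#' used as a scalar summary for comparing networks and tuning integration.
#'
#' @param pr An `fl_prcurve` from [pr_curve()].
#' @return Nonnegative area.
#' @export
pr_area <- function(pr) {
  ok <- !is.na(pr$precision)
  r <- pr$recall[ok]; p <- pr$precision[ok]
  if (length(r) < 2L) return(0)
  sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}

# Mann-Whitney AUC with midrank tie handling
midrank_auc <- function(scores, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out guilt-by-association prioritization
#'
#' Scores every network gene by the summed weight of its links to phenotype
#' member genes other than itself, ranks all network genes by that score,
#' and summarizes how well the ranking recovers the members themselves as
#' the area under the ROC curve (Mann–Whitney midrank formula, members
#' present in the network as positives). Because a member gene's own
#' membership contributes nothing to its score, each member is effectively
#' held out and predicted from the remaining members — leave-one-out
#' cross-validation in one pass. An AUC of 1 is a perfect prediction; 0.5
#' is chance.
#'
#' @param net A [fl_network].
#' @param phenotype Character vector of member genes; at least 2 must be
#'   present in the network. Genes absent from the network are excluded
#'   from the ranking (they have no links to score).
#' @return A list of class `fl_prioritization`: `ranked` (data.frame of
#'   gene, score, is_member, sorted by descending score with canonical
#'   name tie-break), `positives`, `auc`.
#' @export
loo_gba_scores <- function(net, phenotype) {
  stopifnot(inherits(net, "fl_network"))
  phenotype <- unique(toupper(as.character(phenotype)))
  genes <- network_genes(net)
  members <- intersect(phenotype, genes)
  if (length(members) < 2L) {
    stop("fewer than 2 phenotype genes in the network; missing: ",
         paste(setdiff(phenotype, genes), collapse = ", "), call. = FALSE)
  }
  score <- stats::setNames(numeric(length(genes)), genes)
  hit_b <- net$b %in% members
  hit_a <- net$a %in% members
  if (any(hit_b)) {
    s <- tapply(net$weight[hit_b], net$a[hit_b], sum)
    score[names(s)] <- score[names(s)] + s
  }
  if (any(hit_a)) {
    s <- tapply(net$weight[hit_a], net$b[hit_a], sum)
    score[names(s)] <- score[names(s)] + s
  }
  is_member <- genes %in% members
  if (all(is_member)) {
    stop("every network gene is a phenotype member; AUC is undefined", call. = FALSE)
  }
  o <- order(-score, genes)
  structure(list(
    ranked = data.frame(gene = genes[o], score = unname(score[o]),
                        is_member = is_member[o], stringsAsFactors = FALSE),
    positives = members,
    auc = midrank_auc(score, is_member)
  ), class = "fl_prioritization")
}

#' @export
print.fl_prioritization <- function(x, ...) {
  cat(sprintf("<fl_prioritization: %d genes ranked, %d members, AUC %.3f>\n",
              nrow(x$ranked), length(x$positives), x$auc))
  invisible(x)
}

#' Batch leave-one-out AUC over a phenotype collection
#'
#' Runs [loo_gba_scores()] for each set; sets with fewer than two genes in
#' the network are skipped with a message rather than aborting the batch.
#'
#' @param net A [fl_network].
#' @param phenotypes A [gene_set_collection].
#' @return Named numeric vector of AUCs, one per usable set.
#' @export
auc_batch <- function(net, phenotypes) {
  stopifnot(inherits(phenotypes, "fl_genesets"))
  genes <- network_genes(net)
  out <- vapply(names(phenotypes), function(nm) {
    tryCatch(loo_gba_scores(net, phenotypes[[nm]])$auc,
             error = function(e) {
               message("skipping '", nm, "': ", conditionMessage(e))
               NA_real_
             })
  }, 0)
  out <- out[!is.na(out)]
  if (!length(out)) stop("no usable phenotype sets", call. = FALSE)
  out
}

#' Extreme-tail gene sets from a quantitative phenotype parameter
#'
#' Fits a normal location/scale (mean, SD) to one parameter's per-gene
#' values — quantitative phenotype scores are typically approximately
#' normal — and emits up to two candidate sets: genes whose one-sided
#' upper-tail probability falls below `p_threshold`, and likewise for the
#' lower tail. Sets smaller than `min_size` are dropped. With
#' `method = "empirical"` the tails are cut at empirical quantiles instead.
#'
#' @param values Named numeric vector: gene -> parameter value (>= 10
#'   finite values required).
#' @param p_threshold Per-side tail probability, in (0, 0.5); 1e-4 is the
#'   conventional morphology-screen choice.
#' @param min_size Minimum member genes per emitted set (default 5).
#' @param method `"normal"` (default) or `"empirical"`.
#' @param name Stem for the emitted set names (`<name>.upper`,
#'   `<name>.lower`).
#' @return A [gene_set_collection] with 0–2 sets, or `NULL` if none
#'   survives `min_size`.
#' @export
extreme_tail_sets <- function(values, p_threshold = 1e-4, min_size = 5L,
                              method = c("normal", "empirical"),
                              name = "parameter") {
  method <- match.arg(method)
  stopifnot(p_threshold > 0, p_threshold < 0.5, min_size >= 1L)
  values <- values[is.finite(values)]
  if (length(values) < 10L) stop("need >= 10 finite values", call. = FALSE)
  if (is.null(names(values))) stop("values must be named by gene", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance: no tails to cut", call. = FALSE)
  genes <- toupper(names(values))
  if (method == "normal") {
    mu <- mean(values); sigma <- stats::sd(values)
    upper <- genes[stats::pnorm(values, mu, sigma, lower.tail = FALSE) < p_threshold]
    lower <- genes[stats::pnorm(values, mu, sigma, lower.tail = TRUE) < p_threshold]
  } else {
    qs <- stats::quantile(values, c(p_threshold, 1 - p_threshold), names = FALSE)
    upper <- genes[values > qs[2]]
    lower <- genes[values < qs[1]]
  }
  sets <- list(upper, lower)
  names(sets) <- paste0(name, c(".upper", ".lower"))
  sets <- sets[lengths(sets) >= min_size]
  if (!length(sets)) return(NULL)
  gene_set_collection(sets)
}

#' One-sided Wilcoxon signed-rank test for paired AUCs
#'
#' Tests whether the second network's per-phenotype AUCs exceed the
#' first's. Zero differences are dropped; absolute differences are
#' midranked. For n <= 25 retained pairs the exact null distribution of the
#' positive-rank sum is computed by convolution (exact even under ties);
#' above that, a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param auc_a,auc_b Equal-length numeric vectors (>= 5), paired by
#'   phenotype; the alternative is `auc_b > auc_a`.
#' @return One-sided p-value.
#' @export
wilcoxon_signed_rank <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b) || length(auc_a) < 5L) {
    stop("need equal-length paired vectors of length >= 5", call. = FALSE)
  }
  d <- auc_b - auc_a
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero", call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null: distribution of the positive-rank sum over the 2^n sign
    # assignments, via the generating function prod_i (1 + x^{2 r_i})
    # (doubled ranks keep midranks integral)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (ri in r2) {
      f <- f + c(numeric(ri), f[seq_len(total + 1L - ri)])
    }
    w2 <- as.integer(round(2 * W))
    sum(f[(w2 + 1L):(total + 1L)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    stats::pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
}
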