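# Shared fixtures and independent oracles, built in code at test time.

# 100 genes; genes 1-10 form a weight-1 clique; a few weight-1 background
# edges among the remaining 90 keep non-member scores defined.
clique_network <- function() {
  genes <- sprintf("G%03d", 1:100)
  members <- genes[1:10]
  cl <- t(utils::combn(members, 2))
  bg_a <- genes[c(11, 13, 15, 20, 40)]
  bg_b <- genes[c(12, 14, 16, 30, 50)]
  net <- fl_network(c(cl[, 1], bg_a), c(cl[, 2], bg_b),
                    rep(1, nrow(cl) + length(bg_a)), tag = "toy")
  attr(net, "members") <- members
  net
}

# brute-force Mann-Whitney AUC: fraction of (positive, negative) score
# pairs won, plus half ties
auc_oracle <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# brute-force hypergeometric upper tail by combinatorial summation
hyper_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# plug-in mutual information (bits) from the 2x2 joint table, looped
mi_oracle <- function(x, y) {
  tab <- table(factor(x, 0:1), factor(y, 0:1)) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    if (tab[i, j] > 0) s <- s + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
  }
  as.numeric(s)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
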