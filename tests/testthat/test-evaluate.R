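test_that("pr_curve computes cumulative precision and genome-coverage recall", {
  # 4 ranked gold-evaluable links labelled +,-,+,+ in rank order
  net <- fl_network(rep("A", 4), c("B", "C", "D", "E"), c(4, 3, 2, 1), tag = "t")
  gold <- gold_standard(data.frame(a = "A", b = c("B", "D", "E")),
                        data.frame(a = "A", b = "C"))
  pr <- pr_curve(net, gold, bin_size = 2, genome_size = 10)
  expect_equal(pr$pairs_considered, c(2, 4))
  expect_equal(pr$precision, c(0.5, 0.75))

  # recall counts distinct genes over the genome
  net2 <- fl_network(c("A", "C", "A", "E"), c("B", "D", "C", "F"),
                     c(4, 3, 2, 1), tag = "t")
  gold2 <- gold_standard(data.frame(a = c("A", "C"), b = c("B", "D")),
                         data.frame(a = "E", b = "F"))
  pr2 <- pr_curve(net2, gold2, bin_size = 1, genome_size = 6)
  # ranked (A,B),(C,D),(A,C),(E,F): the third link adds no new gene
  expect_equal(pr2$recall, c(2, 4, 4, 6) / 6)
  expect_equal(pr2$recall[nrow(pr2)], 1)

  # all links gold-positive: precision constant at 1
  pr3 <- pr_curve(net2, gold_standard(as.data.frame(net2[, c("a", "b")]),
                                      data.frame(a = "X", b = "Y")),
                  bin_size = 2, genome_size = 6)
  expect_equal(pr3$precision, c(1, 1))

  expect_error(pr_curve(net, gold, bin_size = 2, genome_size = 3), "genome_size")
  expect_error(pr_curve(net2, gold_standard(data.frame(a = "X", b = "Y"),
                                            data.frame(a = "X", b = "Z")),
                        bin_size = 2, genome_size = 6), "gold-evaluable")
})

test_that("pr_curve recall is non-decreasing with terminal coverage", {
  set.seed(4)
  modules <- list(sprintf("G%04d", 1:8))
  net <- make_network(30, modules, p_in = 0.9, p_out = 0.2, seed = 4)
  gold <- make_gold(list(sprintf("G%04d", 1:8), sprintf("G%04d", 9:16)))
  pr <- pr_curve(net, gold, bin_size = 5, genome_size = 40)
  expect_true(all(diff(pr$recall) >= 0))
  expect_true(all(diff(pr$pairs_considered) > 0))
  expect_equal(pr$recall[nrow(pr)], length(network_genes(net)) / 40)
  ok <- !is.na(pr$precision)
  expect_true(all(pr$precision[ok] >= 0 & pr$precision[ok] <= 1))
})

test_that("LOO guilt-by-association hits the AUC boundary cases", {
  net <- clique_network()
  members <- attr(net, "members")
  res <- loo_gba_scores(net, members)
  expect_equal(res$auc, 1)  # clique disconnected from the rest: perfect
  expect_equal(sum(res$ranked$is_member[1:10]), 10L)

  # all scores equal: chance-level AUC by midrank
  flat <- fl_network(rep("H", 5), paste0("N", 1:5), rep(0, 5), tag = "t")
  res2 <- loo_gba_scores(flat, c("N1", "N2"))
  expect_equal(res2$auc, 0.5)
})

test_that("LOO-GBA AUC equals the Mann-Whitney pair-enumeration oracle", {
  # positive scores {3, 1}, negative {2, 0} -> 3/4 by enumeration
  expect_equal(funclink:::midrank_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  set.seed(12)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    scores <- sample(0:5, n, replace = TRUE)  # heavy ties
    pos <- seq_len(n) %in% sample(n, sample(2:(n - 2), 1))
    expect_equal(funclink:::midrank_auc(scores, pos), auc_oracle(scores, pos))
  }
})

test_that("a gene's own phenotype membership never changes its score", {
  net <- make_network(40, list(1:10), p_in = 0.8, p_out = 0.2, seed = 9)
  phen <- sprintf("G%04d", 2:8)
  g <- "G0012"
  s1 <- loo_gba_scores(net, phen)
  s2 <- loo_gba_scores(net, c(phen, g))
  score_of <- function(res, gene) res$ranked$score[res$ranked$gene == gene]
  expect_equal(score_of(s1, g), score_of(s2, g))
})

test_that("auc_batch scores usable sets and skips the rest", {
  net <- clique_network()
  members <- attr(net, "members")
  sets <- gene_set_collection(list(good1 = members, good2 = members,
                                   tiny = c(members[1], "ABSENT")))
  expect_message(res <- auc_batch(net, sets), "skipping 'tiny'")
  expect_equal(unname(res[c("good1", "good2")]), c(1, 1))
  expect_false("tiny" %in% names(res))
  bad <- gene_set_collection(list(x = c("NO1", "NO2")))
  expect_error(suppressMessages(auc_batch(net, bad)), "no usable")
})

test_that("extreme_tail_sets cuts both tails of a fitted normal", {
  set.seed(30)
  vals <- stats::setNames(rnorm(400), sprintf("G%03d", 1:400))
  vals[1:6] <- 10    # planted upper tail
  vals[7:9] <- -10   # planted lower tail, below min_size
  sets <- extreme_tail_sets(vals, p_threshold = 1e-4, min_size = 5,
                            name = "hdm1")
  expect_equal(names(sets), "hdm1.upper")
  expect_setequal(sets$hdm1.upper, sprintf("G%03d", 1:6))

  both <- extreme_tail_sets(vals, p_threshold = 1e-4, min_size = 3,
                            name = "hdm1")
  expect_setequal(names(both), c("hdm1.upper", "hdm1.lower"))
  expect_lte(length(both), 2L)

  # a single extreme gene with min_size 1
  v2 <- stats::setNames(c(rep(0:1, 10), 50), c(sprintf("A%02d", 1:20), "OUT"))
  single <- extreme_tail_sets(v2, p_threshold = 0.01, min_size = 1,
                              name = "p")
  expect_equal(single$p.upper, "OUT")

  expect_error(extreme_tail_sets(stats::setNames(rep(1, 20), paste0("g", 1:20))),
               "zero variance")
  expect_error(extreme_tail_sets(stats::setNames(rnorm(5), paste0("g", 1:5))),
               ">= 10")
})

test_that("wilcoxon_signed_rank gives exact one-sided p-values", {
  expect_equal(wilcoxon_signed_rank(rep(0, 5), 1:5), 1 / 32)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
  # agreement with the reference implementation when ties are absent
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(12)
    b <- a + rnorm(12, 0.3)
    ref <- stats::wilcox.test(b, a, paired = TRUE, alternative = "greater",
                              exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank(a, b), ref, tolerance = 1e-12)
  }
  # large-sample branch: strong consistent improvement is significant
  set.seed(22)
  a <- rnorm(40)
  expect_lt(wilcoxon_signed_rank(a, a + 1), 1e-6)
})

test_that("null wilcoxon p-values are approximately uniform", {
  set.seed(23)
  p <- replicate(300, {
    a <- rnorm(20)
    wilcoxon_signed_rank(a, a + rnorm(20))
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(p), 0.4)
  expect_lt(mean(p), 0.6)
})
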