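test_that("hypergeom_tail matches enumeration and handles boundaries", {
  expect_equal(hypergeom_tail(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_tail(0, 5, 4, 10), 1)   # total probability
  expect_equal(hypergeom_tail(3, 3, 3, 3), 1)    # degenerate universe
  expect_error(hypergeom_tail(5, 4, 10, 10), "out of order")
  expect_error(hypergeom_tail(1, 5, 4, 3), "out of order")
})

test_that("hypergeom_tail agrees with brute-force mass summation", {
  for (N in c(5, 9, 17, 33, 60)) {
    for (K in unique(round(seq(0, N, length.out = 6)))) {
      for (n in unique(round(seq(1, N, length.out = 6)))) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_tail(k, K, n, N), hyper_oracle(k, K, n, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("find_new_members ranks candidates by summed linkage to the query", {
  # candidate X linked to every query member with weight 2
  net <- fl_network(c("X", "X", "X", "Q1", "Y"),
                    c("Q1", "Q2", "Q3", "Q2", "Z"),
                    c(2, 2, 2, 1, 1), tag = "t")
  res <- find_new_members(net, c("Q1", "Q2", "Q3"), top = 10)
  expect_equal(res$gene[1], "X")
  expect_equal(res$score[1], 6)  # w * |query in net|
  expect_false(any(res$gene %in% c("Q1", "Q2", "Q3")))
  # unlinked genes score 0 and rank after all positive scorers
  expect_equal(res$score[res$gene == "Y"], 0)
  expect_gt(which(res$gene == "Y"), which(res$gene == "X"))
  expect_error(find_new_members(net, c("NOPE1", "NOPE2")), "unmatched.*NOPE1")
})

test_that("find_new_members score is additive over disjoint query parts", {
  net <- make_network(40, list(1:12), p_in = 0.7, p_out = 0.2, seed = 14)
  q1 <- sprintf("G%04d", 1:4)
  q2 <- sprintf("G%04d", 5:8)
  full <- find_new_members(net, c(q1, q2), top = 100)
  s1 <- find_new_members(net, q1, top = 100)
  s2 <- find_new_members(net, q2, top = 100)
  common <- Reduce(intersect, list(full$gene, s1$gene, s2$gene))
  f <- function(df) stats::setNames(df$score, df$gene)[common]
  expect_equal(f(full), f(s1) + f(s2))
})

test_that("find_new_members recovers the unseen half of a planted module", {
  hits <- vapply(1:20, function(s) {
    net <- make_network(60, list(1:12), p_in = 0.9, p_out = 0.05, seed = s)
    res <- find_new_members(net, sprintf("G%04d", 1:6), top = 6)
    sum(res$gene %in% sprintf("G%04d", 7:12)) / 6
  }, 0)
  expect_gt(mean(hits), 0.9)
})

test_that("neighbor_sets reads adjacency off the network", {
  star <- fl_network(rep("H", 3), c("A", "B", "C"), rep(1, 3), tag = "t")
  sets <- neighbor_sets(star, include_hub = TRUE)
  expect_setequal(sets$H, c("H", "A", "B", "C"))
  expect_setequal(sets$A, c("A", "H"))
  no_hub <- neighbor_sets(star, include_hub = FALSE)
  expect_setequal(no_hub$H, c("A", "B", "C"))
  expect_equal(length(no_hub), length(network_genes(star)))
  # one set per (non-isolated) gene on random graphs
  for (s in 1:3) {
    net <- make_network(25, list(), p_out = 0.15, seed = s)
    expect_equal(length(neighbor_sets(net, include_hub = FALSE)),
                 length(network_genes(net)))
  }
})

test_that("find_modulators ranks hubs by hypergeometric DEG enrichment", {
  # hub H's neighbor set is exactly the DEG set; K with hub = degs + 1
  net <- fl_network(c(rep("H", 4), "X", "Y"),
                    c(paste0("D", 1:4), "Y", "Z"),
                    rep(1, 6), tag = "t")
  degs <- paste0("D", 1:4)
  res <- find_modulators(net, degs, include_hub = TRUE)
  expect_equal(res$hub[1], "H")
  expect_equal(res$overlap[1], 4L)
  N <- length(network_genes(net))
  expect_equal(res$p_value[1], hyper_oracle(4, 5, 4, N))
  # a hub with zero DEG neighbors sits at p = 1, ranked last
  expect_equal(res$p_value[res$hub == "Z"], 1)
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_error(find_modulators(net, "UNSEEN"), "no DEG")
  expect_error(find_modulators(net, degs, universe_size = 3), "universe_size")
  # explicit genome universe: larger N, smaller tail probability
  res2 <- find_modulators(net, degs, universe_size = 100)
  expect_lt(res2$p_value[1], res$p_value[1])
})

test_that("a non-DEG hub outranks DEG genes when its set is most enriched", {
  net <- make_network(100, list(), p_out = 0.08, seed = 31)
  genes <- network_genes(net)
  deg <- vapply(genes, function(g) sum(net$a == g) + sum(net$b == g), 0L)
  hub <- genes[which.max(deg)]
  degs <- make_deg_query(net, hub, fraction = 1, n_noise = 2, seed = 32)
  expect_false(hub %in% degs)  # the planted modulator shows no "expression change"
  res <- find_modulators(net, degs)
  expect_equal(res$hub[1], hub)
})

test_that("modulator p-values are conservative under random DEG draws", {
  net <- make_network(80, list(), p_out = 0.1, seed = 33)
  genes <- network_genes(net)
  frac <- vapply(1:40, function(s) {
    degs <- funclink:::with_seed(s, sample(genes, 8))
    res <- find_modulators(net, degs)
    mean(res$p_value < 0.1)
  }, 0)
  # discrete tails are valid but conservative: level respected on average
  expect_lte(mean(frac), 0.12)
})

test_that("infer_functions returns the most enriched neighbor annotations", {
  star <- fl_network(rep("H", 4), paste0("N", 1:4), rep(1, 4), tag = "t")
  anns <- gene_set_collection(list(
    exclusive = paste0("N", 1:4),          # exactly the neighbors
    broad = c(paste0("N", 1:4), "H"),
    off = c("H")))
  res <- infer_functions(star, "H", anns, top = 30)
  expect_equal(res$term[1], "exclusive")
  expect_false("off" %in% res$term)  # no neighbor members -> absent
  expect_true(all(diff(res$p_value) >= 0))
  expect_true(all(res$neighbor_hits <= res$term_size))
  expect_error(infer_functions(star, "MISSING", anns), "not in network")
})

test_that("infer_functions truncates to the requested listing size", {
  hub <- "H"
  neigh <- sprintf("N%02d", 1:40)
  net <- fl_network(rep(hub, 40), neigh, rep(1, 40), tag = "t")
  # 50 terms, each hit by some neighbors
  set.seed(41)
  terms <- lapply(1:50, function(i) sample(neigh, 5 + i %% 7))
  names(terms) <- sprintf("T%02d", 1:50)
  anns <- gene_set_collection(terms)
  expect_equal(nrow(infer_functions(net, hub, anns)), 30L)
  expect_equal(nrow(infer_functions(net, hub, anns, top = 7)), 7L)
})

test_that("hypothesis tools are deterministic given their inputs", {
  net <- make_network(50, list(1:10), p_in = 0.8, p_out = 0.1, seed = 44)
  q <- sprintf("G%04d", 1:5)
  expect_identical(find_new_members(net, q), find_new_members(net, q))
  expect_identical(find_modulators(net, q), find_modulators(net, q))
  expect_identical(neighbor_sets(net), neighbor_sets(net))
})
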