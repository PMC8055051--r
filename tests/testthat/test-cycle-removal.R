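triangle <- gene_network(c("a", "b", "c"),
                         data.frame(from = c("a", "b", "c"),
                                    to = c("b", "c", "a")))
two_cycles <- gene_network(c("a", "b", "c", "d"),
                           data.frame(from = c("a", "b", "c", "d"),
                                      to = c("b", "a", "d", "c")))
chain <- gene_network(c("a", "b", "c"),
                      data.frame(from = c("a", "b"), to = c("b", "c")))

test_that("DFS removes exactly the back edges", {
  d <- remove_cycles_dfs(triangle)
  expect_equal(paste(d$removed$from, d$removed$to), "c a")
  expect_false(has_cycle(d$dag))

  d2 <- remove_cycles_dfs(chain)
  expect_equal(nrow(d2$removed), 0L)
  expect_identical(d2$dag, chain)

  d3 <- remove_cycles_dfs(two_cycles)
  expect_equal(nrow(d3$removed), 2L)
  expect_false(has_cycle(d3$dag))
  expect_equal(brute_mfas_size(two_cycles), 2L)
})

test_that("the greedy MFAS heuristic is optimal on the hand fixtures", {
  expect_equal(nrow(remove_cycles_mfas(triangle)$removed), 1L)
  expect_equal(nrow(remove_cycles_mfas(chain)$removed), 0L)
  expect_equal(nrow(remove_cycles_mfas(two_cycles)$removed), 2L)
})

test_that("PageRank scores match symmetry, conservation and igraph", {
  sym <- gene_network(c("a", "b"),
                      data.frame(from = c("a", "b"), to = c("b", "a")))
  sc <- pagerank_scores(sym)
  expect_equal(unname(sc$score), c(0.5, 0.5), tolerance = 1e-8)

  star <- gene_network(c("a", "b", "c", "d"),
                       data.frame(from = c("b", "c", "d"),
                                  to = c("a", "a", "a")))
  s <- pagerank_scores(star)$score
  expect_gt(s[["a"]], s[["b"]])
  expect_equal(s[["b"]], s[["c"]], tolerance = 1e-12)
  expect_equal(s[["c"]], s[["d"]], tolerance = 1e-12)

  for (seed in 61:70) {
    g <- random_gene_network(9, 4L + seed %% 14L, seed = seed)
    s <- pagerank_scores(g, tol = 1e-10)$score
    expect_equal(sum(s), 1, tolerance = 1e-9)
    ig <- igraph::page_rank(
      igraph::graph_from_data_frame(as.data.frame(g$edges[, 1:2]),
                                    directed = TRUE, vertices = g$genes),
      damping = 0.85)$vector
    expect_equal(unname(s), unname(ig[names(s)]), tolerance = 1e-6)
  }
})

test_that("hierarchy removal deletes exactly the order-violating edges", {
  sc <- c(a = 1, b = 2, c = 3)
  expect_equal(nrow(remove_by_hierarchy(chain, sc)$removed), 0L)
  d <- remove_by_hierarchy(triangle, sc)
  expect_equal(paste(d$removed$from, d$removed$to), "c a")
  expect_false(has_cycle(d$dag))
  # all-equal scores: lexicographic tie-break keeps a -> b
  ab <- gene_network(c("a", "b"), data.frame(from = "a", to = "b"))
  expect_equal(nrow(remove_by_hierarchy(ab, c(a = 0, b = 0))$removed), 0L)
  expect_error(remove_by_hierarchy(chain, c(a = 1, b = 2)), "missing")
})

test_that("PageRank cycle removal is acyclic and no-ops on DAGs", {
  expect_equal(nrow(remove_cycles_pagerank(chain)$removed), 0L)
  sym <- gene_network(c("a", "b"),
                      data.frame(from = c("a", "b"), to = c("b", "a")))
  d <- remove_cycles_pagerank(sym)
  expect_equal(nrow(d$removed), 1L)
  expect_false(has_cycle(d$dag))
  for (seed in 81:110) {
    g <- random_gene_network(5L + seed %% 20L,
                             round((5L + seed %% 20L) * 1.6),
                             seed = seed, require_cycle = TRUE)
    expect_false(has_cycle(remove_cycles_pagerank(g)$dag))
  }
})

test_that("TrueSkill rates edge winners above losers, deterministically", {
  ab <- gene_network(c("a", "b"), data.frame(from = "a", to = "b"))
  s <- trueskill_scores(ab, seed = 3)$score
  expect_gt(s[["b"]], s[["a"]])

  s2 <- trueskill_scores(chain, epochs = 10, seed = 3)$score
  expect_true(s2[["a"]] < s2[["b"]] && s2[["b"]] < s2[["c"]])

  g <- random_gene_network(10, 18, seed = 9, require_cycle = TRUE)
  expect_identical(trueskill_scores(g, seed = 42),
                   trueskill_scores(g, seed = 42))
})

test_that("agony of a ranking follows the formula", {
  ab <- gene_network(c("a", "b"), data.frame(from = "a", to = "b"))
  expect_equal(agony_of_ranking(ab, c(a = 0, b = 1)), 0)
  expect_equal(agony_of_ranking(ab, c(a = 0, b = 0)), 1)
  expect_equal(agony_of_ranking(triangle, c(a = 0, b = 1, c = 2)), 3)
  expect_error(agony_of_ranking(ab, c(a = 0.5, b = 1)), "integer")
})

test_that("the agony heuristic achieves zero on DAGs and optimum on a 2-cycle", {
  r <- min_agony_ranking(chain)
  expect_equal(agony_of_ranking(chain, r), 0)
  # a 2-cycle: one direction can be free only if the other costs >= 2,
  # and equal ranks cost 1 + 1, so the exhaustive optimum is 2
  sym <- gene_network(c("a", "b"),
                      data.frame(from = c("a", "b"), to = c("b", "a")))
  opt <- brute_agony(sym)
  expect_equal(opt, 2)
  expect_equal(agony_of_ranking(sym, min_agony_ranking(sym)), opt)
})

test_that("the ensemble removes one optimal edge from a triangle", {
  expect_equal(brute_mfas_size(triangle), 1L)
  d <- remove_cycles_ensemble(triangle, seed = 1)
  expect_equal(nrow(d$removed), 1L)
  expect_false(has_cycle(d$dag))
  expect_equal(nrow(remove_cycles_ensemble(chain, seed = 1)$removed), 0L)
})

test_that("every ensemble-removed edge lay on a cycle at removal time", {
  for (seed in 121:140) {
    g <- random_gene_network(5L + seed %% 11L,
                             round((5L + seed %% 11L) * 1.7),
                             seed = seed, require_cycle = TRUE)
    d <- remove_cycles_ensemble(g, seed = seed)
    expect_false(has_cycle(d$dag))
    # replay the removals, checking cycle membership before each one
    kept <- g$edges
    if (nrow(d$removed) > 0L) {
      for (i in seq_len(nrow(d$removed))) {
        on_cyc <- kegg2net:::edges_on_cycles(kept$from, kept$to)
        j <- which(kept$from == d$removed$from[i] &
                     kept$to == d$removed$to[i])
        expect_true(on_cyc[j])
        kept <- kept[-j, ]
      }
    }
  }
})

test_that("all methods partition the edges, keep signs and are deterministic", {
  for (seed in 141:160) {
    n <- 5L + seed %% 13L
    g <- random_gene_network(n, round(n * 1.5), seed = seed,
                             signed = TRUE, require_cycle = TRUE)
    for (meth in c("dfs", "mfas", "pr", "en")) {
      d <- remove_cycles(g, meth, seed = seed)
      expect_false(has_cycle(d$dag))
      expect_identical(d$dag$genes, g$genes)
      all_edges <- rbind(as.data.frame(d$dag$edges),
                         as.data.frame(d$removed))
      all_edges <- all_edges[order(all_edges$from, all_edges$to,
                                   method = "radix"), ]
      rownames(all_edges) <- NULL
      expect_identical(all_edges, as.data.frame(g$edges))
      expect_identical(d, remove_cycles(g, meth, seed = seed))
    }
  }
})
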