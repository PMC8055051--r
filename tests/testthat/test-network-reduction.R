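hg <- function(kinds, edges = NULL) {
  kegg2net:::hetero_graph(
    data.frame(name = names(kinds), kind = unname(kinds)), edges)
}

test_that("indirect relations through non-gene chains become edges", {
  # one compound in between
  h1 <- hg(c(g1 = "gene", C = "compound", g2 = "gene"),
           data.frame(from = c("g1", "C"), to = c("C", "g2")))
  expect_equal(edge_strings(collapse_to_gene_network(h1)), "g1 g2")
  # a two-compound chain
  h2 <- hg(c(g1 = "gene", C1 = "compound", C2 = "compound", g2 = "gene"),
           data.frame(from = c("g1", "C1", "C2"), to = c("C1", "C2", "g2")))
  expect_equal(edge_strings(collapse_to_gene_network(h2)), "g1 g2")
})

test_that("paths through an intermediate gene do not create shortcut edges", {
  h <- hg(c(g1 = "gene", g2 = "gene", g3 = "gene"),
          data.frame(from = c("g1", "g3"), to = c("g3", "g2")))
  expect_equal(edge_strings(collapse_to_gene_network(h)),
               c("g1 g3", "g3 g2"))
})

test_that("self-loops through compounds are suppressed", {
  h <- hg(c(g1 = "gene", C = "compound"),
          data.frame(from = c("g1", "C"), to = c("C", "g1")))
  net <- collapse_to_gene_network(h)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$genes, "g1")
})

test_that("indirect signs follow the product rule and ambiguity is unknown", {
  two_hop <- function(s1, s2) {
    h <- hg(c(a = "gene", C = "compound", b = "gene"),
            data.frame(from = c("a", "C"), to = c("C", "b"),
                       sign = c(s1, s2)))
    collapse_to_gene_network(h)$edges$sign
  }
  expect_equal(two_hop("activating", "activating"), "activating")
  expect_equal(two_hop("inhibiting", "activating"), "inhibiting")
  expect_equal(two_hop("inhibiting", "inhibiting"), "activating")
  expect_equal(two_hop("activating", "unknown"), "unknown")
  # two parallel routes with conflicting products
  h <- hg(c(a = "gene", C = "compound", D = "compound", b = "gene"),
          data.frame(from = c("a", "C", "a", "D"),
                     to = c("C", "b", "D", "b"),
                     sign = c("activating", "activating",
                              "activating", "inhibiting")))
  expect_equal(collapse_to_gene_network(h)$edges$sign, "unknown")
})

test_that("collapse preserves direct edges, the gene set, and is idempotent", {
  for (seed in 21:30) {
    h <- random_hetero(seed)
    net <- collapse_to_gene_network(h)
    genes_h <- h$nodes$name[h$nodes$kind == "gene"]
    expect_identical(net$genes, genes_h)
    direct <- h$edges[h$edges$from %in% genes_h & h$edges$to %in% genes_h, ]
    expect_true(all(paste(direct$from, direct$to) %in%
                      paste(net$edges$from, net$edges$to)))
    # idempotence: a gene-only graph collapses to itself
    h2 <- kegg2net:::hetero_graph(
      data.frame(name = net$genes, kind = "gene"), net$edges)
    expect_true(kegg2net:::network_equal(collapse_to_gene_network(h2), net))
  }
})

test_that("adding an edge never removes a collapsed edge (monotonicity)", {
  for (seed in 31:36) {
    h <- random_hetero(seed)
    if (nrow(h$nodes) < 3L) next
    before <- edge_strings(collapse_to_gene_network(h))
    withr::with_seed(seed + 100L, {
      pick <- sample(h$nodes$name, 2L)
    })
    h2 <- kegg2net:::hetero_graph(
      h$nodes, rbind(as.data.frame(h$edges),
                     data.frame(from = pick[1], to = pick[2],
                                sign = "unknown")))
    after <- edge_strings(collapse_to_gene_network(h2))
    expect_true(all(before %in% after))
  }
})

test_that("nonisolated_count counts genes with any incident edge", {
  expect_equal(nonisolated_count(gene_network()), 0L)
  g <- gene_network(c("a", "b", "c"), data.frame(from = "a", to = "b"))
  expect_equal(nonisolated_count(g), 2L)
  g2 <- random_gene_network(10, 12, seed = 5)
  touched <- unique(c(g2$edges$from, g2$edges$to))
  expect_equal(nonisolated_count(g2), length(touched))
})

test_that("has_cycle detects directed cycles of length >= 2", {
  path3 <- gene_network(c("a", "b", "c"),
                        data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_false(has_cycle(path3))
  tri <- gene_network(c("a", "b", "c"),
                      data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "a")))
  expect_true(has_cycle(tri))
  g8 <- gene_network(sprintf("n%d", 1:8),
                     data.frame(from = c("n1", "n2", "n3", "n4"),
                                to = c("n2", "n1", "n4", "n5")))
  expect_true(has_cycle(g8))
  # cross-check against igraph on random fixtures
  for (seed in 41:50) {
    g <- random_gene_network(8, 4L + seed %% 12L, seed = seed)
    ig <- igraph::graph_from_data_frame(
      as.data.frame(g$edges[, 1:2]), directed = TRUE, vertices = g$genes)
    expect_equal(has_cycle(g), !igraph::is_dag(ig))
  }
})

test_that("SIF serialization matches the dialect and keeps isolated nodes", {
  g <- gene_network(c("a", "b", "z"),
                    data.frame(from = "a", to = "b", sign = "activating"))
  txt <- serialize_network(g, "sif")
  expect_equal(txt, "a\tactivation\tb\nz\n")
  back <- parse_network(txt, "sif")
  expect_identical(back, g)
})

test_that("adjacency serialization is the 0/1 header dialect", {
  g <- gene_network(c("a", "b"), data.frame(from = "a", to = "b"))
  txt <- serialize_network(g, "adjacency")
  expect_equal(strsplit(txt, "\n")[[1]],
               c("\ta\tb", "a\t0\t1", "b\t0\t0"))
  empty3 <- parse_network("\ta\tb\tc\na\t0\t0\t0\nb\t0\t0\t0\nc\t0\t0\t0\n",
                          "adjacency")
  expect_equal(empty3$genes, c("a", "b", "c"))
  expect_equal(nrow(empty3$edges), 0L)
})

test_that("malformed network text errors name the offending line", {
  expect_error(parse_network("a\tactivation\n", "sif"), "line 1")
  expect_error(parse_network("a\tbogus\tb\n", "sif"), "bogus")
  expect_error(parse_network("\ta\tb\na\t0\nb\t0\t0\n", "adjacency"),
               "line 2")
  expect_error(parse_network("\ta\tb\na\t0\t2\nb\t0\t0\n", "adjacency"),
               "non-binary")
})

test_that("serialize -> parse is the identity on random networks", {
  for (seed in 51:75) {
    g_signed <- random_gene_network(4L + seed %% 7L, seed %% 8L,
                                    seed = seed, signed = TRUE)
    expect_identical(parse_network(serialize_network(g_signed, "sif"),
                                   "sif"), g_signed)
    g_plain <- random_gene_network(6, seed %% 10L, seed = seed + 500L)
    expect_identical(parse_network(serialize_network(g_plain, "adjacency"),
                                   "adjacency"), g_plain)
  }
})
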