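# Independent brute-force oracles and fixture helpers. Each oracle is a
# direct transcription of the definition it checks, kept free of the
# package's own algorithmic shortcuts.

# All-simple-paths collapse oracle: gene pair (g, t) is connected iff some
# simple path g -> ... -> t has only non-gene internal nodes. Returns the
# sorted "from to" strings.
oracle_collapse_edges <- function(h) {
  nodes <- h$nodes$name
  kind <- stats::setNames(h$nodes$kind, nodes)
  genes <- nodes[kind[nodes] == "gene"]
  adj <- split(h$edges$to, factor(h$edges$from, levels = nodes))
  res <- character(0)
  for (g in genes) {
    reached <- character(0)
    walk <- function(v, visited) {
      for (w in adj[[v]]) {
        if (w %in% visited) next
        if (kind[[w]] == "gene") {
          if (w != g) reached <<- union(reached, w)
        } else {
          walk(w, c(visited, w))
        }
      }
    }
    walk(g, g)
    for (t in sort(reached, method = "radix")) {
      res <- c(res, paste(g, t))
    }
  }
  sort(res, method = "radix")
}

# Exact minimum feedback arc set size: minimise backward edges over all
# vertex permutations (valid because some optimal FAS is realised by a
# linear order).
brute_mfas_size <- function(g) {
  if (nrow(g$edges) == 0L) return(0L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- nrow(g$edges)
  for (p in perms(g$genes)) {
    pos <- stats::setNames(seq_along(p), p)
    best <- min(best, sum(pos[g$edges$from] > pos[g$edges$to]))
  }
  best
}

# Exact minimum agony: exhaustive search over all rank vectors in
# {0..n-1}^n, vectorised over the grid.
brute_agony <- function(g) {
  n <- length(g$genes)
  if (nrow(g$edges) == 0L) return(0)
  grid <- as.matrix(expand.grid(rep(list(0:(n - 1L)), n)))
  colnames(grid) <- g$genes
  cost <- numeric(nrow(grid))
  for (i in seq_len(nrow(g$edges))) {
    cost <- cost + pmax(0, grid[, g$edges$from[i]] -
                          grid[, g$edges$to[i]] + 1)
  }
  min(cost)
}

# Independent multinomial BIC: nested loops over observed parent configs
# and target states, written without the package's tabulation shortcut.
brute_local_bic <- function(target, parents, data) {
  N <- ncol(data)
  x <- data[target, ]
  states <- unique(x)
  r <- length(states)
  configs <- if (length(parents) == 0L) {
    list(rep(TRUE, N))
  } else {
    key <- apply(matrix(data[parents, , drop = FALSE],
                        nrow = length(parents)), 2, paste, collapse = "/")
    lapply(unique(key), function(k) key == k)
  }
  ll <- 0
  for (sel in configs) {
    Nj <- sum(sel)
    for (st in states) {
      Njk <- sum(x[sel] == st)
      if (Njk > 0L) ll <- ll + Njk * log(Njk / Nj)
    }
  }
  ll - log(N) / 2 * length(configs) * (r - 1L)
}

# Random heterogeneous graph over mixed node kinds.
random_hetero <- function(seed, n_max = 12L) {
  withr::with_seed(seed, {
    n <- sample(3:n_max, 1L)
    kinds <- sample(c("gene", "compound", "map", "enzyme"), n,
                    replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
    nodes <- data.frame(name = sprintf("n%02d", seq_len(n)), kind = kinds)
    m <- sample(0:(2L * n), 1L)
    e <- NULL
    if (m > 0L) {
      e <- data.frame(from = sample(nodes$name, m, replace = TRUE),
                      to = sample(nodes$name, m, replace = TRUE))
      e <- e[e$from != e$to, , drop = FALSE]
    }
    kegg2net:::hetero_graph(nodes, e)
  })
}

# Enumerate every digraph (edge subset, no self-loops) on the given genes.
all_digraphs <- function(genes) {
  pairs <- expand.grid(from = genes, to = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  np <- nrow(pairs)
  lapply(0:(2^np - 1L), function(s) {
    sel <- which(bitwAnd(s, 2^(0:(np - 1L))) > 0)
    gene_network(genes, pairs[sel, , drop = FALSE])
  })
}

# Minimal hand-built kinetic model (bypasses assign_kinetics) for exact
# fixed-point checks.
manual_kinetics <- function(g, edge_params, basal) {
  structure(list(network = g,
                 edge_params = tibble::as_tibble(edge_params),
                 basal = basal),
            class = "kinetic_model")
}

edge_strings <- function(g) {
  if (nrow(g$edges) == 0L) return(character(0))
  sort(paste(g$edges$from, g$edges$to), method = "radix")
}
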