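#' @name cycle_removal
#' @title Converting a cyclic gene network into a DAG
#'
#' @description
#' Bayesian-network scoring requires a directed acyclic graph, but gene
#' interaction networks deduced from pathway maps frequently contain
#' feedback loops. Four alternative strategies convert a cyclic
#' [gene_network] into a DAG, each returning a `dag_result` that records the
#' acyclic network, the ordered list of removed edges and the method tag:
#'
#' * [remove_cycles_dfs()] — depth-first search; every back edge (an edge
#'   into a node on the current traversal stack) is deleted. Fast and
#'   simple, but removal count depends on traversal order.
#' * [remove_cycles_mfas()] — the Eades–Lin–Smyth greedy heuristic for the
#'   (NP-hard) minimum feedback arc set problem; tries to minimise the
#'   number of edges removed.
#' * [remove_cycles_pagerank()] — ranks genes by PageRank, then removes all
#'   edges violating the hierarchy; both score orientations are tried and
#'   the cheaper one kept.
#' * [remove_cycles_ensemble()] — votes of two hierarchies (TrueSkill skill
#'   ratings and a minimum-agony integer ranking) pick edges to delete, one
#'   at a time, restricted to edges that still lie on a cycle.
#'
#' The hierarchy convention is uniform: scores increase along edge
#' direction (an edge `u -> v` asserts that `v` outranks `u`), and an edge
#' with `score(u) >= score(v)` violates the hierarchy. All tie-breaking is
#' lexicographic on gene names, so every method is deterministic given its
#' seed.
NULL

new_dag_result <- function(method, dag, removed) {
  structure(list(method = method, dag = dag, removed = removed),
            class = "dag_result")
}

#' @export
print.dag_result <- function(x, ...) {
  cat(sprintf("<dag_result> method=%s: %d edges kept, %d removed\n",
              x$method, nrow(x$dag$edges), nrow(x$removed)))
  invisible(x)
}

# Split g's edges into kept/removed by an index vector into g$edges rows;
# `order` fixes the reported removal order.
dag_result_from_removal <- function(g, method, removed_idx) {
  keep <- setdiff(seq_len(nrow(g$edges)), removed_idx)
  dag <- gene_network(g$genes, g$edges[keep, , drop = FALSE])
  new_dag_result(method, dag, g$edges[removed_idx, , drop = FALSE])
}

#' Remove cycles by depth-first-search back-edge deletion
#'
#' Runs an iterative DFS starting from every gene in lexicographic order
#' (neighbours also expanded lexicographically). An edge pointing at a node
#' currently on the DFS stack is a back edge — exactly the cycle-closing
#' edges — and is removed; tree, forward and cross edges are kept.
#'
#' @param g A [gene_network] (acyclic input is allowed and returns zero
#'   removals).
#' @return A `dag_result` with method tag `"dfs"`.
#' @export
remove_cycles_dfs <- function(g) {
  stopifnot(inherits(g, "gene_network"))
  n <- length(g$genes)
  efrom <- match(g$edges$from, g$genes)
  eto <- match(g$edges$to, g$genes)
  # genes sorted => edge rows sorted by (from,to) => adjacency lists are in
  # lexicographic target order already
  out_adj <- split(seq_along(efrom), factor(efrom, levels = seq_len(n)))
  color <- integer(n)  # 0 white, 1 on stack, 2 done
  removed <- integer(0)
  for (root in seq_len(n)) {
    if (color[root] != 0L) next
    stack_node <- root
    stack_ptr <- 1L  # next out-edge index to try, per stack level
    color[root] <- 1L
    while (length(stack_node) > 0L) {
      top <- length(stack_node)
      v <- stack_node[top]
      edges_v <- out_adj[[v]]
      if (stack_ptr[top] <= length(edges_v)) {
        ei <- edges_v[stack_ptr[top]]
        stack_ptr[top] <- stack_ptr[top] + 1L
        w <- eto[ei]
        if (color[w] == 1L) {
          removed <- c(removed, ei)  # back edge
        } else if (color[w] == 0L) {
          color[w] <- 1L
          stack_node <- c(stack_node, w)
          stack_ptr <- c(stack_ptr, 1L)
        }
      } else {
        color[v] <- 2L
        stack_node <- stack_node[-top]
        stack_ptr <- stack_ptr[-top]
      }
    }
  }
  dag_result_from_removal(g, "dfs", removed)
}

#' Remove cycles by a greedy local MFAS heuristic
#'
#' Builds a vertex sequence with the Eades–Lin–Smyth greedy rule — while
#' nodes remain, sinks are pulled into the right block, sources into the
#' left block, otherwise the node maximising out-degree minus in-degree
#' moves to the left block (ties lexicographic throughout) — then refines
#' the sequence by deterministic insertion local search (each node in turn
#' is moved to the position minimising the number of right-to-left edges,
#' from both the greedy sequence and its reversal, keeping the better
#' result). Edges pointing right-to-left in the final sequence form the
#' feedback arc set and are removed. The refinement never increases the
#' removal count, so for digraphs with no two-cycles the Eades guarantee
#' of at most `m/2 - n/6` removals is preserved.
#'
#' @param g A [gene_network].
#' @return A `dag_result` with method tag `"mfas"`.
#' @export
remove_cycles_mfas <- function(g) {
  stopifnot(inherits(g, "gene_network"))
  n <- length(g$genes)
  if (n == 0L) return(dag_result_from_removal(g, "mfas", integer(0)))
  efrom <- match(g$edges$from, g$genes)
  eto <- match(g$edges$to, g$genes)
  alive_node <- rep(TRUE, n)
  alive_edge <- rep(TRUE, length(efrom))
  outdeg <- tabulate(efrom, nbins = n)
  indeg <- tabulate(eto, nbins = n)
  s1 <- integer(0); s2 <- integer(0)
  drop_node <- function(v) {
    alive_node[v] <<- FALSE
    for (ei in which(alive_edge)) {
      if (efrom[ei] == v || eto[ei] == v) {
        alive_edge[ei] <<- FALSE
        outdeg[efrom[ei]] <<- outdeg[efrom[ei]] - 1L
        indeg[eto[ei]] <<- indeg[eto[ei]] - 1L
      }
    }
  }
  while (any(alive_node)) {
    repeat {  # sinks (incl. isolated) -> prepend to right block
      sinks <- which(alive_node & outdeg == 0L)
      if (length(sinks) == 0L) break
      v <- sinks[1L]  # lexicographically smallest (index order = lex order)
      s2 <- c(v, s2)
      drop_node(v)
    }
    repeat {  # sources -> append to left block
      sources <- which(alive_node & indeg == 0L)
      if (length(sources) == 0L) break
      v <- sources[1L]
      s1 <- c(s1, v)
      drop_node(v)
    }
    rest <- which(alive_node)
    if (length(rest) > 0L) {
      delta <- outdeg[rest] - indeg[rest]
      v <- rest[which.max(delta)]  # which.max keeps first (lex) on ties
      s1 <- c(s1, v)
      drop_node(v)
    }
  }
  seq0 <- c(s1, s2)
  fwd <- refine_sequence(seq0, efrom, eto)
  bwd <- refine_sequence(rev(seq0), efrom, eto)
  best <- if (bwd$cost < fwd$cost) bwd else fwd
  pos <- integer(n)
  pos[best$seq] <- seq_len(n)
  removed <- which(pos[efrom] > pos[eto])
  dag_result_from_removal(g, "mfas", removed)
}

# Deterministic insertion local search on a vertex sequence: sweep nodes in
# index (lexicographic) order, move each to the position minimising the
# backward-edge count (strict improvement only, earliest best position),
# until a sweep makes no change.
refine_sequence <- function(seqv, efrom, eto, max_sweeps = 50L) {
  cost_of <- function(sq) {
    pos <- integer(length(sq))
    pos[sq] <- seq_along(sq)
    sum(pos[efrom] > pos[eto])
  }
  cur <- cost_of(seqv)
  n <- length(seqv)
  if (n >= 2L && length(efrom) > 0L) {
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (v in seq_len(n)) {  # node index order = lexicographic
        i <- match(v, seqv)
        rest <- seqv[-i]
        best_c <- cur
        best_s <- NULL
        for (j in seq_len(n)) {
          if (j == i) next
          s2 <- append(rest, v, after = j - 1L)
          c2 <- cost_of(s2)
          if (c2 < best_c) {
            best_c <- c2
            best_s <- s2
          }
        }
        if (!is.null(best_s)) {
          seqv <- best_s
          cur <- best_c
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  list(seq = seqv, cost = cur)
}

#' PageRank scores for a gene network
#'
#' Standard PageRank by power iteration: uniform teleport over all genes,
#' dangling-node mass redistributed uniformly, iterated until the maximum
#' absolute score change drops below `tol`. Scores sum to one.
#'
#' @param g A non-empty [gene_network].
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param tol Convergence tolerance on the max absolute change; default
#'   `1e-10`.
#' @return A `node_scores` object: list with `method = "pagerank"` and
#'   `score`, a named numeric vector over all genes.
#' @export
pagerank_scores <- function(g, damping = 0.85, tol = 1e-10) {
  stopifnot(inherits(g, "gene_network"), length(g$genes) > 0L,
            damping > 0, damping < 1, tol > 0)
  n <- length(g$genes)
  efrom <- match(g$edges$from, g$genes)
  eto <- match(g$edges$to, g$genes)
  outdeg <- tabulate(efrom, nbins = n)
  # column-stochastic transition matrix (dense; pathway networks are small)
  P <- matrix(0, n, n)
  if (length(efrom) > 0L) {
    for (i in seq_along(efrom)) {
      P[eto[i], efrom[i]] <- P[eto[i], efrom[i]] + 1 / outdeg[efrom[i]]
    }
  }
  dangling_nodes <- outdeg == 0L
  x <- rep(1 / n, n)
  for (iter in seq_len(10000L)) {
    dangling <- sum(x[dangling_nodes])
    x_new <- damping * (as.vector(P %*% x) + dangling / n) +
      (1 - damping) / n
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  structure(list(method = "pagerank",
                 score = stats::setNames(x, g$genes)),
            class = "node_scores")
}

#' Remove the edges violating a node hierarchy
#'
#' Orders the genes by ascending score (ties broken lexicographically,
#' giving a strict total order) and removes exactly the edges that point
#' from a later node to an earlier node. By construction the surviving
#' edges all agree with a topological order, so the result is acyclic.
#'
#' @param g A [gene_network].
#' @param scores A `node_scores` object or a named numeric vector covering
#'   every gene of `g`.
#' @param method Method tag recorded on the result (default `"pr"`).
#' @return A `dag_result`.
#' @export
remove_by_hierarchy <- function(g, scores, method = "pr") {
  stopifnot(inherits(g, "gene_network"))
  s <- if (inherits(scores, "node_scores")) scores$score else scores
  if (!all(g$genes %in% names(s))) {
    stop("scores missing for gene(s): ",
         paste(setdiff(g$genes, names(s)), collapse = ", "), call. = FALSE)
  }
  s <- s[g$genes]
  ord <- order(s, seq_along(s))  # genes sorted, so index breaks ties lex
  pos <- integer(length(s))
  pos[ord] <- seq_along(ord)
  efrom <- match(g$edges$from, g$genes)
  eto <- match(g$edges$to, g$genes)
  removed <- which(pos[efrom] > pos[eto])
  dag_result_from_removal(g, method, removed)
}

#' Remove cycles via a PageRank hierarchy
#'
#' Computes [pagerank_scores()] (damping 0.85, tolerance 1e-10) and applies
#' [remove_by_hierarchy()] under both the ascending and the descending
#' score order, returning whichever removes fewer edges (ties favour
#' ascending). Both orientations are tried because PageRank mass can flow
#' either down or up a regulatory hierarchy depending on the network's
#' edge semantics. An already-acyclic input is returned unchanged (the
#' PageRank order of a DAG need not be topological, and no edge of a DAG
#' needs removing).
#'
#' @param g A [gene_network].
#' @return A `dag_result` with method tag `"pr"`.
#' @export
remove_cycles_pagerank <- function(g) {
  stopifnot(inherits(g, "gene_network"))
  if (length(g$genes) == 0L || !has_cycle(g)) {
    return(dag_result_from_removal(g, "pr", integer(0)))
  }
  sc <- pagerank_scores(g)
  asc <- remove_by_hierarchy(g, sc$score, method = "pr")
  desc <- remove_by_hierarchy(g, -sc$score, method = "pr")
  if (nrow(desc$removed) < nrow(asc$removed)) desc else asc
}

#' TrueSkill skill ratings over a gene network
#'
#' Treats every edge `u -> v` as a two-player match won by `v` (scores
#' increase along edges) and applies the standard two-player no-draw
#' TrueSkill mean/variance updates. Priors are the canonical defaults
#' (mu0 = 25, sigma0 = 25/3, performance noise beta = sigma0/2, dynamics
#' tau = sigma0/100). Each epoch processes all edges once in an order
#' shuffled by the seeded generator.
#'
#' @param g A [gene_network].
#' @param epochs Number of passes over the edge list; default 10.
#' @param seed Integer seed for the per-epoch edge shuffles.
#' @return A `node_scores` object with `method = "trueskill"` and
#'   `score` = the posterior means.
#' @export
trueskill_scores <- function(g, epochs = 10L, seed = 1L) {
  stopifnot(inherits(g, "gene_network"), epochs >= 1L)
  n <- length(g$genes)
  mu0 <- 25; sigma0 <- 25 / 3
  beta2 <- (sigma0 / 2)^2
  tau2 <- (sigma0 / 100)^2
  mu <- rep(mu0, n)
  sig2 <- rep(sigma0^2, n)
  efrom <- match(g$edges$from, g$genes)
  eto <- match(g$edges$to, g$genes)
  m <- length(efrom)
  if (m > 0L) {
    withr::with_seed(seed, {
      for (ep in seq_len(epochs)) {
        for (ei in sample.int(m)) {
          w <- eto[ei]; l <- efrom[ei]  # target of the edge wins
          sig2[w] <- sig2[w] + tau2
          sig2[l] <- sig2[l] + tau2
          c2 <- 2 * beta2 + sig2[w] + sig2[l]
          cc <- sqrt(c2)
          t <- (mu[w] - mu[l]) / cc
          denom <- stats::pnorm(t)
          v <- if (denom < 1e-300) -t else stats::dnorm(t) / denom
          wgt <- v * (v + t)
          mu[w] <- mu[w] + sig2[w] / cc * v
          mu[l] <- mu[l] - sig2[l] / cc * v
          sig2[w] <- sig2[w] * max(1 - sig2[w] / c2 * wgt, 1e-12)
          sig2[l] <- sig2[l] * max(1 - sig2[l] / c2 * wgt, 1e-12)
        }
      }
    })
  }
  structure(list(method = "trueskill",
                 score = stats::setNames(mu, g$genes),
                 sigma = stats::setNames(sqrt(sig2), g$genes)),
            class = "node_scores")
}

#' Social agony of an integer node ranking
#'
#' For integer rank levels `r`, each edge `u -> v` contributes
#' `max(0, r(u) - r(v) + 1)`: an edge climbing at least one level costs
#' nothing, a flat or downward edge is penalised by how far it violates the
#' hierarchy. The agony of a graph under a ranking is the sum over edges.
#'
#' @param g A [gene_network].
#' @param ranks A `node_scores` object or named vector of non-negative
#'   integer rank levels covering all genes.
#' @return A non-negative number.
#' @export
agony_of_ranking <- function(g, ranks) {
  stopifnot(inherits(g, "gene_network"))
  r <- if (inherits(ranks, "node_scores")) ranks$score else ranks
  if (!all(g$genes %in% names(r))) {
    stop("ranks missing for gene(s): ",
         paste(setdiff(g$genes, names(r)), collapse = ", "), call. = FALSE)
  }
  r <- r[g$genes]
  if (any(r < 0) || any(r != round(r))) {
    stop("ranks must be non-negative integers", call. = FALSE)
  }
  if (nrow(g$edges) == 0L) return(0)
  sum(pmax(0, r[g$edges$from] - r[g$edges$to] + 1))
}

#' Heuristic minimum-agony ranking
#'
#' Finds integer rank levels with low [agony_of_ranking()]: ranks are
#' initialised to longest-path levels of the DFS-derived DAG (which gives
#' agony zero on any acyclic input), then refined by single-node moves —
#' each gene in turn is placed at the rank level minimising its incident
#' agony (a convex piecewise-linear function of its rank) — until a full
#' sweep makes no improvement, for at most `max_sweeps` sweeps.
#'
#' @param g A [gene_network].
#' @param max_sweeps Maximum local-search sweeps; default 100.
#' @return A `node_scores` object with `method = "agony"` and integer rank
#'   levels as `score`.
#' @export
min_agony_ranking <- function(g, max_sweeps = 100L) {
  stopifnot(inherits(g, "gene_network"))
  n <- length(g$genes)
  if (n == 0L) {
    return(structure(list(method = "agony",
                          score = stats::setNames(numeric(0), character(0))),
                     class = "node_scores"))
  }
  dag <- remove_cycles_dfs(g)$dag
  topo <- topological_order(dag)
  r <- stats::setNames(integer(n), g$genes)
  for (v in topo) {  # longest-path level in the DFS DAG
    preds <- dag$edges$from[dag$edges$to == v]
    if (length(preds) > 0L) r[v] <- max(r[preds]) + 1L
  }
  efrom <- g$edges$from
  eto <- g$edges$to
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (v in g$genes) {
      ins <- r[efrom[eto == v]]    # ranks of regulators of v
      outs <- r[eto[efrom == v]]   # ranks of targets of v
      if (length(ins) + length(outs) == 0L) next
      cand <- 0:(max(r) + 1L)
      cost <- vapply(cand, function(rv) {
        sum(pmax(0, ins - rv + 1)) + sum(pmax(0, rv - outs + 1))
      }, numeric(1))
      best <- cand[which.min(cost)]  # smallest rank on ties
      cur <- sum(pmax(0, ins - r[v] + 1)) + sum(pmax(0, r[v] - outs + 1))
      if (cost[which.min(cost)] < cur) {
        r[v] <- best
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  structure(list(method = "agony", score = r), class = "node_scores")
}

#' Remove cycles by the TrueSkill + agony ensemble
#'
#' Two hierarchies are computed: TrueSkill posterior means
#' ([trueskill_scores()], 10 epochs) and the minimum-agony integer ranking
#' ([min_agony_ranking()]). Each edge `u -> v` collects one vote per
#' hierarchy that it violates (`score(u) >= score(v)`), plus a violation
#' magnitude (the sum of `score(u) - score(v)` over the voting
#' hierarchies). Edges are then deleted one at a time — always an edge that
#' still lies on a directed cycle, chosen by highest votes, then largest
#' magnitude, then lexicographic `(source, target)` — until the network is
#' acyclic. Re-checking cycle membership after every deletion ensures no
#' unnecessary edge is removed.
#'
#' @param g A [gene_network].
#' @param seed Seed passed to [trueskill_scores()].
#' @return A `dag_result` with method tag `"en"`.
#' @export
remove_cycles_ensemble <- function(g, seed = 1L) {
  stopifnot(inherits(g, "gene_network"))
  m <- nrow(g$edges)
  if (m == 0L) return(dag_result_from_removal(g, "en", integer(0)))
  ts <- trueskill_scores(g, epochs = 10L, seed = seed)$score
  ag <- min_agony_ranking(g)$score
  efrom <- g$edges$from
  eto <- g$edges$to
  viol_ts <- ts[efrom] >= ts[eto]
  viol_ag <- ag[efrom] >= ag[eto]
  votes <- as.integer(viol_ts) + as.integer(viol_ag)
  mag <- ifelse(viol_ts, ts[efrom] - ts[eto], 0) +
    ifelse(viol_ag, ag[efrom] - ag[eto], 0)

  alive <- rep(TRUE, m)
  removed <- integer(0)
  repeat {
    on_cycle <- edges_on_cycles(efrom[alive], eto[alive])
    if (!any(on_cycle)) break
    cand <- which(alive)[on_cycle]
    ord <- order(-votes[cand], -mag[cand], efrom[cand], eto[cand],
                 method = "radix")
    pick <- cand[ord[1L]]
    removed <- c(removed, pick)
    alive[pick] <- FALSE
  }
  dag_result_from_removal(g, "en", removed)
}

# Logical vector: which of the given edges lie on a directed cycle (i.e.
# have both endpoints in the same strongly connected component). SCCs via
# igraph.
edges_on_cycles <- function(from, to) {
  if (length(from) == 0L) return(logical(0))
  verts <- unique(c(from, to))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = verts)
  comp <- igraph::components(ig, mode = "strong")$membership
  comp[from] == comp[to]
}

#' Dispatch a cycle-removal method by tag
#'
#' @param g A [gene_network].
#' @param method One of `"dfs"`, `"mfas"`, `"pr"`, `"en"`.
#' @param seed Seed (used by `"en"` only).
#' @return A `dag_result`.
#' @export
remove_cycles <- function(g, method = c("dfs", "mfas", "pr", "en"),
                          seed = 1L) {
  method <- match.arg(method)
  switch(method,
         dfs = remove_cycles_dfs(g),
         mfas = remove_cycles_mfas(g),
         pr = remove_cycles_pagerank(g),
         en = remove_cycles_ensemble(g, seed = seed))
}
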