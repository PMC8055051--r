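#' Local multinomial BIC of one gene given its parents
#'
#' The decomposable multinomial-network BIC in the higher-is-better sign
#' convention: `sum_jk N_jk log(N_jk / N_j) - (log N)/2 * q * (r - 1)`,
#' where `r` is the number of observed states of the target, `q` the
#' number of observed parent configurations (1 with no parents), and
#' `N_jk` the count of samples with parent configuration `j` and target
#' state `k` (`0 log 0 = 0`; natural log). States and configurations are
#' counted from the data, not from a declared alphabet, so a constant gene
#' contributes exactly 0.
#'
#' @param target Gene name (a row of `data`).
#' @param parents Character vector of parent gene names (possibly empty);
#'   must not contain `target`.
#' @param data Integer matrix of discrete levels, genes x samples.
#' @return The local BIC (a real number, `<= 0`).
#' @export
local_bic <- function(target, parents, data) {
  if (target %in% parents) {
    stop("`parents` must not contain the target gene", call. = FALSE)
  }
  stopifnot(target %in% rownames(data),
            all(parents %in% rownames(data)))
  N <- ncol(data)
  x <- data[target, ]
  r <- length(unique(x))
  if (length(parents) == 0L) {
    counts <- table(x)
    ll <- sum(counts * log(counts / N))
    q <- 1L
  } else {
    pconf <- do.call(paste, c(lapply(parents, function(p) data[p, ]),
                              sep = "\r"))
    tab <- table(pconf, x)
    Nj <- rowSums(tab)
    nz <- tab > 0
    ll <- sum(tab[nz] * log(tab[nz] / Nj[row(tab)[nz]]))
    q <- nrow(tab)
  }
  ll - log(N) / 2 * q * (r - 1L)
}

#' BIC score of a DAG against a discrete expression dataset
#'
#' Sums [local_bic()] over all genes of the DAG with their parent sets.
#' Decomposable: changing one gene's parent set changes only that gene's
#' local term. Higher is better.
#'
#' @param dag An acyclic [gene_network] whose genes all appear in the data.
#' @param data An `expression_dataset` with the discrete matrix filled, or
#'   a discrete genes x samples integer matrix.
#' @return The total BIC (a real number).
#' @export
bic_score <- function(dag, data) {
  stopifnot(inherits(dag, "gene_network"))
  if (inherits(data, "expression_dataset")) {
    if (is.null(data$discrete)) {
      stop("dataset not discretized; call discretize() first", call. = FALSE)
    }
    data <- data$discrete
  }
  if (has_cycle(dag)) {
    cyc <- find_cycle(dag)
    stop("graph is cyclic (e.g. ", paste(cyc, collapse = " -> "),
         "); BIC requires a DAG", call. = FALSE)
  }
  missing <- setdiff(dag$genes, rownames(data))
  if (length(missing) > 0L) {
    stop("gene(s) absent from the data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(vapply(dag$genes, function(v) {
    local_bic(v, dag$edges$from[dag$edges$to == v], data)
  }, numeric(1)))
}

# Return the node names of some directed cycle (for error messages).
find_cycle <- function(g) {
  ig <- igraph::graph_from_data_frame(
    as.data.frame(g$edges[, c("from", "to")]), directed = TRUE,
    vertices = g$genes)
  comp <- igraph::components(ig, mode = "strong")
  big <- which(comp$csize >= 2L)[1L]
  names(comp$membership)[comp$membership == big]
}

#' Sample a random DAG with fixed node and edge counts
#'
#' Draws a uniformly random permutation of the genes, then `n_edges`
#' distinct ordered pairs uniformly among the forward pairs of that
#' permutation. The result is acyclic with exactly the requested node and
#' edge counts — the null model used to judge whether a pathway-derived
#' DAG fits expression data better than chance.
#'
#' @param genes Character vector of gene names.
#' @param n_edges Number of edges, at most `n(n-1)/2`.
#' @param seed Integer seed.
#' @return An acyclic [gene_network].
#' @export
sample_random_dag <- function(genes, n_edges, seed = 1L) {
  genes <- as.character(genes)
  n <- length(genes)
  max_edges <- n * (n - 1L) / 2L
  if (n_edges > max_edges) {
    stop("n_edges (", n_edges, ") exceeds n(n-1)/2 = ", max_edges,
         call. = FALSE)
  }
  withr::with_seed(seed, {
    perm <- sample(genes)
    if (n_edges > 0L) {
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      pick <- pairs[sample(nrow(pairs), n_edges), , drop = FALSE]
      edges <- tibble::tibble(from = perm[pick[, 1L]],
                              to = perm[pick[, 2L]],
                              sign = "unknown")
    } else {
      edges <- NULL
    }
  })
  gene_network(genes, edges)
}

#' Dense descending rank of the four method scores
#'
#' Rank 1 is the best (highest) BIC; tied scores share the better rank.
#'
#' @param method_scores Named numeric vector with exactly the four entries
#'   `dfs`, `mfas`, `pr`, `en`.
#' @return Named integer vector of ranks 1..4 (with ties).
#' @export
rank_scores <- function(method_scores) {
  expected <- c("dfs", "mfas", "pr", "en")
  if (!setequal(names(method_scores), expected) ||
      length(method_scores) != 4L) {
    stop("`method_scores` must be named exactly dfs, mfas, pr, en",
         call. = FALSE)
  }
  vals <- sort(unique(method_scores), decreasing = TRUE)
  stats::setNames(match(method_scores, vals), names(method_scores))
}

# Dense ascending rank with ties sharing the better (smaller) rank; used
# for the edges-removed ranking.
dense_rank_asc <- function(x) {
  vals <- sort(unique(x))
  stats::setNames(match(x, vals), names(x))
}

#' Count random DAGs beating a score
#'
#' Strictly-greater comparison: ties do not count against the score.
#'
#' @param score The method DAG's BIC.
#' @param random_scores Numeric vector of random-DAG BICs.
#' @return Integer count in `0..length(random_scores)`.
#' @export
rank_against_randoms <- function(score, random_scores) {
  sum(random_scores > score)
}
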