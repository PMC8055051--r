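#' Collapse a heterogeneous pathway graph to a gene-only network
#'
#' Produces the directed gene interaction network that preserves every
#' direct and indirect gene-gene relation of the pathway graph: an edge
#' `g1 -> g2` is present iff the heterogeneous graph contains a directed
#' path from `g1` to `g2` whose internal nodes (if any) are all non-gene
#' entities (compounds, maps, enzymes, ...). All non-gene nodes are then
#' dropped; gene nodes are kept even when isolated. Self-loops (a gene
#' reaching itself through non-gene nodes) are suppressed, since DAG
#' conversion and Bayesian-network scoring forbid them.
#'
#' The sign of an indirect edge is the product of signs along the mediating
#' path when every hop has a known sign and all mediating routes agree;
#' any ambiguity (an unknown hop, or routes with conflicting products)
#' yields `"unknown"`. Sign propagation is computed as a fixpoint over the
#' achievable sign products at each non-gene node, so it considers walks:
#' a sign-ambiguous cycle among non-gene nodes conservatively yields
#' `"unknown"`.
#'
#' @param h A `hetero_graph` from [build_hetero_graph()].
#' @return A [gene_network] whose gene set is exactly the gene-kind nodes of
#'   `h`.
#' @export
collapse_to_gene_network <- function(h) {
  stopifnot(inherits(h, "hetero_graph"))
  genes <- h$nodes$name[h$nodes$kind == "gene"]
  if (length(genes) == 0L) return(gene_network())
  is_gene <- stats::setNames(h$nodes$kind == "gene", h$nodes$name)

  n_nodes <- nrow(h$nodes)
  idx <- stats::setNames(seq_len(n_nodes), h$nodes$name)
  efrom <- idx[h$edges$from]
  eto <- idx[h$edges$to]
  esign <- sign_to_num(h$edges$sign)
  out_adj <- split(seq_along(efrom), factor(efrom, levels = seq_len(n_nodes)))

  res_from <- character(0); res_to <- character(0); res_sign <- character(0)
  for (g in genes) {
    # reach[[v]] = set of achievable sign products (subset of {-1,0,1}) of
    # walks g -> ... -> v whose internal nodes are all non-gene
    reach <- vector("list", n_nodes)
    queue <- integer(0)
    push <- function(v, s) {
      if (!(s %in% reach[[v]])) {
        reach[[v]] <<- c(reach[[v]], s)
        if (!is_gene[[h$nodes$name[v]]]) queue <<- c(queue, v)
      }
    }
    for (ei in out_adj[[idx[[g]]]]) push(eto[ei], esign[ei])
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (ei in out_adj[[v]]) {
        for (s in reach[[v]]) {
          push(eto[ei], if (s == 0L || esign[ei] == 0L) 0L else s * esign[ei])
        }
      }
    }
    for (v in seq_len(n_nodes)) {
      nm <- h$nodes$name[v]
      if (!is_gene[[nm]] || nm == g || is.null(reach[[v]])) next
      s <- unique(reach[[v]])
      res_from <- c(res_from, g)
      res_to <- c(res_to, nm)
      res_sign <- c(res_sign,
                    if (length(s) == 1L) num_to_sign(s) else "unknown")
    }
  }
  gene_network(genes, tibble::tibble(from = res_from, to = res_to,
                                     sign = res_sign))
}
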