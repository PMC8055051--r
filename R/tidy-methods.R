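#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gene network into its edge table
#'
#' @param x A [gene_network].
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `sign`.
#' @export
tidy.gene_network <- function(x, ...) x$edges

#' One-row summary of a gene network
#'
#' @param x A [gene_network].
#' @param ... Unused.
#' @return A tibble: `n_genes`, `n_edges`, `n_nonisolated`, `cyclic`.
#' @export
glance.gene_network <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), n_edges = nrow(x$edges),
                 n_nonisolated = nonisolated_count(x),
                 cyclic = has_cycle(x))
}

#' Tidy a DAG result into an edge table with removal status
#'
#' @param x A `dag_result`.
#' @param ... Unused.
#' @return A tibble `from`, `to`, `sign`, `status` (`"kept"`/`"removed"`).
#' @export
tidy.dag_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$dag$edges, status = "kept"),
    dplyr::mutate(x$removed, status = "removed"))
}

#' One-row summary of a DAG result
#'
#' @param x A `dag_result`.
#' @param ... Unused.
#' @return A tibble: `method`, `n_genes`, `n_kept`, `n_removed`, `acyclic`.
#' @export
glance.dag_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_genes = length(x$dag$genes),
                 n_kept = nrow(x$dag$edges), n_removed = nrow(x$removed),
                 acyclic = !has_cycle(x$dag))
}

#' Tidy node scores into a table
#'
#' @param x A `node_scores`.
#' @param ... Unused.
#' @return A tibble `gene`, `method`, `score`.
#' @export
tidy.node_scores <- function(x, ...) {
  tibble::tibble(gene = names(x$score), method = x$method,
                 score = unname(x$score))
}

#' Tidy an expression dataset into long form
#'
#' @param x An `expression_dataset`.
#' @param ... Unused.
#' @return A long tibble `gene`, `sample`, `value` and, if discretized,
#'   `level`.
#' @export
tidy.expression_dataset <- function(x, ...) {
  out <- tibble::as_tibble(x$continuous, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value")
  if (!is.null(x$discrete)) {
    lv <- tibble::as_tibble(x$discrete, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "level")
    out <- dplyr::left_join(out, lv, by = c("gene", "sample"))
  }
  out
}

#' Per-method summary of a benchmark table
#'
#' @param x A `kegg2net_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return The summary tibble attached by [run_benchmark()] (one row per
#'   method: mean edges removed, mean removal rank, mean score rank, mean
#'   randoms beating).
#' @export
glance.kegg2net_benchmark <- function(x, ...) attr(x, "summary")

#' Plot the four benchmark summary panels
#'
#' Bar panels per cycle-removal method: mean edges removed, mean rank by
#' edges removed, mean BIC-score rank among the methods, and mean number
#' of random DAGs scoring above the method's DAG.
#'
#' @param object A `kegg2net_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kegg2net_benchmark <- function(object, ...) {
  s <- attr(object, "summary")
  long <- tidyr::pivot_longer(
    s, c("mean_edges_removed", "mean_removal_rank",
         "mean_score_rank", "mean_randoms_beating"),
    names_to = "panel", values_to = "value")
  long$panel <- factor(long$panel,
                       levels = c("mean_edges_removed", "mean_removal_rank",
                                  "mean_score_rank", "mean_randoms_beating"),
                       labels = c("Mean edges removed",
                                  "Mean rank (edges removed)",
                                  "Mean BIC rank (methods)",
                                  "Mean random DAGs beating"))
  long$method <- factor(toupper(long$method),
                        levels = c("DFS", "MFAS", "PR", "EN"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$method, y = .data$value,
                               fill = .data$method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cycle-removal method comparison") +
    ggplot2::theme_minimal()
}

#' Plot an expression dataset as a heat tile map
#'
#' @param object An `expression_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expression_dataset <- function(object, ...) {
  long <- tidy.expression_dataset(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "sample", y = NULL, fill = "level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom rlang .data
NULL
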