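#' Sample Hill-kinetics parameters for a network
#'
#' Equips every edge of a gene network with a Hill transfer function
#' (coefficient `n` in 1..10, half-saturation `K` in \[0.05, 1\], role
#' activator or repressor) and every gene with a basal expression level
#' `b` in \[0.01, 0.2\]. Signed edges force the role (activating ->
#' activator, inhibiting -> repressor); unknown-sign edges sample it. The
#' result is deterministic given the network and seed.
#'
#' @param g A [gene_network].
#' @param seed Integer seed.
#' @return A `kinetic_model`: list with `network`, `edge_params` (tibble:
#'   `from`, `to`, `n`, `K`, `role`) and `basal` (named numeric).
#' @export
assign_kinetics <- function(g, seed = 1L) {
  stopifnot(inherits(g, "gene_network"))
  m <- nrow(g$edges)
  withr::with_seed(seed, {
    role <- character(m)
    if (m > 0L) {
      role[g$edges$sign == "activating"] <- "activator"
      role[g$edges$sign == "inhibiting"] <- "repressor"
      unk <- which(g$edges$sign == "unknown")
      role[unk] <- sample(c("activator", "repressor"), length(unk),
                          replace = TRUE)
    }
    edge_params <- tibble::tibble(
      from = g$edges$from, to = g$edges$to,
      n = if (m) sample(1:10, m, replace = TRUE) else integer(0),
      K = if (m) stats::runif(m, 0.05, 1.0) else numeric(0),
      role = role)
    basal <- stats::setNames(stats::runif(length(g$genes), 0.01, 0.2),
                             g$genes)
  })
  structure(list(network = g, edge_params = edge_params, basal = basal),
            class = "kinetic_model")
}

#' Solve network steady-state expression levels
#'
#' Regulated genes follow
#' `f(v) = clip01( b_v + (1 - b_v) * mean_e h_e(x_u) )` over incoming edges
#' `e = (u, v)`, where `h` is the Hill activation `x^n / (K^n + x^n)` for
#' activators and `K^n / (K^n + x^n)` for repressors. Regulator-free
#' (root) genes are clamped at the supplied input levels. A damped
#' synchronous iteration `x <- (1 - alpha) x + alpha f(x)` runs from 0.5
#' until the maximum change drops below `tol` or `max_iter` is reached;
#' cyclic networks may oscillate, hence the damping and the convergence
#' flag on the result.
#'
#' @param m A `kinetic_model` from [assign_kinetics()].
#' @param inputs Named numeric vector of expression levels in \[0, 1\]
#'   covering exactly the regulator-free genes.
#' @param alpha Damping in (0, 1\]; default 0.5.
#' @param tol Convergence tolerance; default 1e-8.
#' @param max_iter Iteration cap; default 500.
#' @return Named numeric vector of levels over all genes, with attribute
#'   `converged` (logical).
#' @export
steady_state <- function(m, inputs, alpha = 0.5, tol = 1e-8,
                         max_iter = 500L) {
  stopifnot(inherits(m, "kinetic_model"), alpha > 0, alpha <= 1)
  g <- m$network
  roots <- setdiff(g$genes, unique(g$edges$to))
  if (!setequal(names(inputs), roots)) {
    stop("`inputs` must cover exactly the regulator-free genes: ",
         paste(roots, collapse = ", "), call. = FALSE)
  }
  x <- stats::setNames(rep(0.5, length(g$genes)), g$genes)
  x[roots] <- inputs[roots]
  regulated <- setdiff(g$genes, roots)
  ep <- m$edge_params
  in_edges <- split(seq_len(nrow(ep)), factor(ep$to, levels = g$genes))
  hill <- function(x, n, K, role) {
    a <- x^n / (K^n + x^n)
    ifelse(role == "activator", a, 1 - a)
  }
  converged <- length(regulated) == 0L
  for (it in seq_len(max_iter)) {
    if (length(regulated) == 0L) break
    fx <- x
    for (v in regulated) {
      ei <- in_edges[[v]]
      h <- hill(x[ep$from[ei]], ep$n[ei], ep$K[ei], ep$role[ei])
      val <- m$basal[[v]] + (1 - m$basal[[v]]) * mean(h)
      fx[v] <- min(1, max(0, val))
    }
    x_new <- x
    x_new[regulated] <- (1 - alpha) * x[regulated] + alpha * fx[regulated]
    delta <- max(abs(x_new[regulated] - x[regulated]))
    x <- x_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  attr(x, "converged") <- converged
  x
}

#' Generate a synthetic steady-state expression dataset
#'
#' For each sample, regulator-free gene levels are drawn uniform(0, 1),
#' the network steady state is solved with [steady_state()], Gaussian
#' measurement noise is added and values are clipped to \[0, 1\]. The data
#' therefore reflects the regulatory topology: regulated genes co-vary
#' with their regulators through the Hill transfer functions.
#'
#' @param m A `kinetic_model`.
#' @param n_samples Number of samples (columns).
#' @param noise_sd Gaussian noise standard deviation; default 0.05.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param alpha,tol,max_iter Passed to [steady_state()].
#' @return An `expression_dataset`: list with `genes`, `continuous`
#'   (genes x samples matrix), `discrete` (`NULL` until [discretize()]),
#'   and `converged` (logical per sample).
#' @export
generate_expression <- function(m, n_samples, noise_sd = 0.05, seed = 1L,
                                alpha = 0.5, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(m, "kinetic_model"), n_samples >= 1L, noise_sd >= 0)
  g <- m$network
  roots <- setdiff(g$genes, unique(g$edges$to))
  n <- length(g$genes)
  mat <- matrix(NA_real_, n, n_samples,
                dimnames = list(g$genes,
                                sprintf("s%03d", seq_len(n_samples))))
  converged <- logical(n_samples)
  withr::with_seed(seed, {
    for (j in seq_len(n_samples)) {
      inputs <- stats::setNames(stats::runif(length(roots)), roots)
      x <- steady_state(m, inputs, alpha = alpha, tol = tol,
                        max_iter = max_iter)
      converged[j] <- attr(x, "converged")
      mat[, j] <- x[g$genes]
    }
    if (noise_sd > 0) {
      mat <- mat + matrix(stats::rnorm(n * n_samples, 0, noise_sd),
                          n, n_samples)
    }
  })
  mat <- pmin(pmax(mat, 0), 1)  # first arg keeps the dim attributes
  structure(list(genes = g$genes, continuous = mat, discrete = NULL,
                 converged = converged),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (%s; %d/%d converged)\n",
              length(x$genes), ncol(x$continuous),
              if (is.null(x$discrete)) "continuous" else "discretized",
              sum(x$converged), length(x$converged)))
  invisible(x)
}

#' Discretize expression into equal-frequency levels
#'
#' Per gene, continuous values are quantile-binned into `levels`
#' categories labelled `0..levels-1` (equal-frequency binning, the
#' conventional preparation of expression data for multinomial
#' Bayesian-network scoring). Ties at a bin boundary go to the lower bin;
#' a constant gene maps to all zeros.
#'
#' @param d An `expression_dataset` with the continuous matrix present.
#' @param levels Number of bins, at least 2; default 3.
#' @return The dataset with its `discrete` matrix filled.
#' @export
discretize <- function(d, levels = 3L) {
  stopifnot(inherits(d, "expression_dataset"), levels >= 2L)
  ns <- ncol(d$continuous)
  if (levels > ns) {
    stop("`levels` (", levels, ") exceeds the sample count (", ns, ")",
         call. = FALSE)
  }
  disc <- t(apply(d$continuous, 1L, function(x) {
    qs <- stats::quantile(x, probs = seq_len(levels - 1L) / levels,
                          names = FALSE)
    rowSums(outer(x, qs, ">"))
  }))
  dimnames(disc) <- dimnames(d$continuous)
  storage.mode(disc) <- "integer"
  d$discrete <- disc
  d
}

#' Write an expression dataset to TSV
#'
#' Genes as rows (first column `gene`), samples as columns. The discrete
#' matrix, if present, is written alongside with suffix `.disc.tsv`.
#'
#' @param d An `expression_dataset`.
#' @param path Output path for the continuous matrix (`.tsv`).
#' @return Invisibly, the path(s) written.
#' @export
write_expression <- function(d, path) {
  stopifnot(inherits(d, "expression_dataset"))
  write_mat <- function(m, p) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(d$continuous, path)
  out <- path
  if (!is.null(d$discrete)) {
    p2 <- sub("\\.tsv$", ".disc.tsv", path)
    if (identical(p2, path)) p2 <- paste0(path, ".disc.tsv")
    write_mat(d$discrete, p2)
    out <- c(out, p2)
  }
  invisible(out)
}
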