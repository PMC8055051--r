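#' Construct a directed gene-only interaction network
#'
#' A `gene_network` is a directed graph over gene identifiers, the unit that
#' the whole pipeline operates on: the collapse of a pathway graph produces
#' one, the cycle-removal methods consume and return them, and the simulator
#' and BIC scorer read their topology. Genes are stored in a canonical
#' (radix-sorted) order which fixes the adjacency-matrix row/column order;
#' edges are unique per ordered pair and may carry a regulatory sign.
#' Self-loops are not representable: Bayesian-network scoring and DAG
#' conversion both forbid them.
#'
#' @param genes Character vector of gene identifiers. Isolated genes (degree
#'   zero) are legitimate members.
#' @param edges A data frame with columns `from`, `to` and optionally `sign`
#'   (one of `"activating"`, `"inhibiting"`, `"unknown"`; default
#'   `"unknown"`). Duplicate ordered pairs are merged; conflicting signs
#'   collapse to `"unknown"`.
#'
#' @return An object of class `gene_network`: a list with elements `genes`
#'   (character) and `edges` (a tibble with columns `from`, `to`, `sign`).
#' @examples
#' g <- gene_network(c("a", "b", "c"),
#'                   data.frame(from = "a", to = "b", sign = "activating"))
#' nonisolated_count(g)
#' has_cycle(g)
#' @export
gene_network <- function(genes = character(), edges = NULL) {
  genes <- sort_lex(unique(as.character(genes)))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(),
                            sign = character())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!all(c("from", "to") %in% names(edges))) {
      stop("`edges` must have columns `from` and `to`", call. = FALSE)
    }
    if (!"sign" %in% names(edges)) edges$sign <- "unknown"
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    bad_sign <- setdiff(unique(edges$sign), SIGN_LEVELS)
    if (length(bad_sign) > 0L) {
      stop("unknown edge sign(s): ", paste(bad_sign, collapse = ", "),
           call. = FALSE)
    }
    missing <- setdiff(unique(c(edges$from, edges$to)), genes)
    if (length(missing) > 0L) {
      stop("edge endpoint(s) not in `genes`: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(edges$from == edges$to)) {
      stop("self-loops are not allowed in a gene_network", call. = FALSE)
    }
    edges <- edges |>
      dplyr::summarise(
        sign = if (dplyr::n_distinct(.data$sign) == 1L) .data$sign[1L]
               else "unknown",
        .by = c("from", "to")
      )
    edges <- edges[order(edges$from, edges$to, method = "radix"),
                   c("from", "to", "sign")]
  }
  structure(list(genes = genes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes, %d edges (%d non-isolated%s)\n",
              length(x$genes), nrow(x$edges), nonisolated_count(x),
              if (has_cycle(x)) ", cyclic" else ""))
  if (nrow(x$edges) > 0L) print(utils::head(x$edges, 10L))
  invisible(x)
}

#' Number of non-isolated genes in a network
#'
#' Counts the genes with total degree (in + out) of at least one. Pathway
#' networks below a minimum non-isolated size are too small for a meaningful
#' DAG-fitness comparison and are skipped by [run_pathway()] (default
#' threshold 6).
#'
#' @param g A [gene_network].
#' @return A non-negative integer.
#' @export
nonisolated_count <- function(g) {
  stopifnot(inherits(g, "gene_network"))
  length(unique(c(g$edges$from, g$edges$to)))
}

#' Test a network for directed cycles
#'
#' Kahn's algorithm: repeatedly strip indegree-zero nodes; a cycle exists iff
#' some node can never be stripped. Self-loops are excluded by construction,
#' so any cycle found has length at least two.
#'
#' @param g A [gene_network].
#' @return `TRUE` iff `g` contains a directed cycle.
#' @export
has_cycle <- function(g) {
  stopifnot(inherits(g, "gene_network"))
  is.null(topological_order(g))
}

# Kahn topological sort; NULL if cyclic. Deterministic (lexicographic queue).
topological_order <- function(g) {
  n <- length(g$genes)
  if (n == 0L) return(character())
  from <- match(g$edges$from, g$genes)
  to <- match(g$edges$to, g$genes)
  indeg <- tabulate(to, nbins = n)
  out_adj <- split(to, factor(from, levels = seq_len(n)))
  avail <- which(indeg == 0L)  # genes sorted, so index order is lex order
  res <- integer(0)
  while (length(avail) > 0L) {
    v <- avail[1L]
    avail <- avail[-1L]
    res <- c(res, v)
    for (w in out_adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(res) < n) NULL else g$genes[res]
}

#' Serialize a network to SIF or adjacency-matrix text
#'
#' SIF (simple interaction file, the Cytoscape dialect) writes one
#' tab-separated `source  relation  target` line per edge, where the relation
#' token encodes the sign (`activation`, `inhibition`, `interaction` for
#' unknown); isolated genes are emitted as bare single-token lines so the
#' node set round-trips. The adjacency dialect is tab-separated with gene
#' names as first row and first column and 0/1 cells (signs are not
#' representable and are read back as unknown).
#'
#' @param g A [gene_network].
#' @param format `"sif"` or `"adjacency"`.
#' @return A single string (lines joined by `"\n"`, trailing newline).
#' @seealso [parse_network()] for the inverse.
#' @export
serialize_network <- function(g, format = c("sif", "adjacency")) {
  stopifnot(inherits(g, "gene_network"))
  format <- match.arg(format)
  if (format == "sif") {
    rel <- c(activating = "activation", inhibiting = "inhibition",
             unknown = "interaction")
    lines <- character(0)
    if (nrow(g$edges) > 0L) {
      lines <- paste(g$edges$from, rel[g$edges$sign], g$edges$to, sep = "\t")
    }
    isolated <- setdiff(g$genes, unique(c(g$edges$from, g$edges$to)))
    lines <- c(lines, isolated)
    paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
  } else {
    n <- length(g$genes)
    m <- matrix(0L, n, n, dimnames = list(g$genes, g$genes))
    if (nrow(g$edges) > 0L) {
      m[cbind(match(g$edges$from, g$genes), match(g$edges$to, g$genes))] <- 1L
    }
    header <- paste(c("", g$genes), collapse = "\t")
    rows <- vapply(seq_len(n), function(i) {
      paste(c(g$genes[i], m[i, ]), collapse = "\t")
    }, character(1))
    paste0(paste(c(header, rows), collapse = "\n"), "\n")
  }
}

#' Parse a network from SIF or adjacency-matrix text
#'
#' Inverse of [serialize_network()] on its image. Malformed lines (SIF lines
#' with two tokens or more than three, ragged adjacency rows, non-binary
#' cells) raise an error naming the offending line number.
#'
#' @param text A single string or character vector of lines.
#' @param format `"sif"` or `"adjacency"`.
#' @return A [gene_network].
#' @export
parse_network <- function(text, format = c("sif", "adjacency")) {
  format <- match.arg(format)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else as.character(text)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (format == "sif") {
    sign_of <- c(activation = "activating", inhibition = "inhibiting",
                 interaction = "unknown")
    genes <- character(0)
    from <- character(0); to <- character(0); sgn <- character(0)
    for (i in seq_along(lines)) {
      if (lines[i] == "") next
      tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(tok) == 1L) {
        genes <- c(genes, tok)
      } else if (length(tok) == 3L) {
        if (!tok[2] %in% names(sign_of)) {
          stop(sprintf("SIF line %d: unknown relation '%s'", i, tok[2]),
               call. = FALSE)
        }
        from <- c(from, tok[1]); to <- c(to, tok[3])
        sgn <- c(sgn, sign_of[[tok[2]]])
        genes <- c(genes, tok[1], tok[3])
      } else {
        stop(sprintf("SIF line %d: expected 1 or 3 tab-separated fields, got %d",
                     i, length(tok)), call. = FALSE)
      }
    }
    gene_network(genes, tibble::tibble(from = from, to = to, sign = sgn))
  } else {
    if (length(lines) == 0L) return(gene_network())
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    genes <- header[-1]
    n <- length(genes)
    if (length(lines) - 1L != n) {
      stop(sprintf("adjacency matrix: %d gene columns but %d data rows",
                   n, length(lines) - 1L), call. = FALSE)
    }
    from <- character(0); to <- character(0)
    for (i in seq_len(n)) {
      tok <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
      if (length(tok) != n + 1L) {
        stop(sprintf("adjacency line %d: expected %d fields, got %d",
                     i + 1L, n + 1L, length(tok)), call. = FALSE)
      }
      cells <- tok[-1]
      if (!all(cells %in% c("0", "1"))) {
        stop(sprintf("adjacency line %d: non-binary cell", i + 1L),
             call. = FALSE)
      }
      hit <- which(cells == "1")
      from <- c(from, rep(tok[1], length(hit)))
      to <- c(to, genes[hit])
    }
    gene_network(genes, tibble::tibble(from = from, to = to,
                                       sign = rep("unknown", length(from))))
  }
}

# Structural equality (canonical form makes identical() sufficient, but keep
# an explicit comparator for clarity in tests and round-trip checks).
network_equal <- function(a, b, check_sign = TRUE) {
  if (!identical(a$genes, b$genes)) return(FALSE)
  ea <- a$edges; eb <- b$edges
  if (nrow(ea) != nrow(eb)) return(FALSE)
  cols <- if (check_sign) c("from", "to", "sign") else c("from", "to")
  identical(as.data.frame(ea[cols]), as.data.frame(eb[cols]))
}
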