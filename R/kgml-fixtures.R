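#' Describe a synthetic KGML pathway scenario
#'
#' A compact description of a pathway from which [kgml_build()] emits a
#' syntactically valid KGML document. Used to exercise the full pipeline
#' without downloading anything from KEGG, and by the `fixtures` CLI
#' command.
#'
#' @param genes Named list: entry id -> character vector of gene
#'   identifiers (an entry may carry several).
#' @param compounds,maps,orthologs Named lists: entry id -> identifier.
#' @param groups Named list: entry id -> character vector of member entry
#'   ids.
#' @param relations Data frame with columns `source`, `target`, `subtype`
#'   and optionally `compound` (an entry id; `NA` for none). Subtype
#'   `"compound"` routes the relation through that compound entry.
#' @param reactions Data frame with columns `id`, `name`, `substrate`,
#'   `product`, `enzyme` (entry id of the catalysing gene entry) and
#'   `reversible` (logical).
#' @param pathway_id,title Pathway accession and display name.
#' @return A `kgml_scenario` list.
#' @export
kgml_scenario <- function(genes = list(), compounds = list(), maps = list(),
                          orthologs = list(), groups = list(),
                          relations = NULL, reactions = NULL,
                          pathway_id = "path:syn00001",
                          title = "synthetic pathway") {
  structure(list(genes = genes, compounds = compounds, maps = maps,
                 orthologs = orthologs, groups = groups,
                 relations = relations, reactions = reactions,
                 pathway_id = pathway_id, title = title),
            class = "kgml_scenario")
}

#' Emit KGML XML text for a scenario
#'
#' @param scenario A [kgml_scenario()].
#' @return A single string of KGML XML (UTF-8).
#' @export
kgml_build <- function(scenario) {
  stopifnot(inherits(scenario, "kgml_scenario"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<pathway name="%s" org="syn" number="00001" title="%s">',
            esc(scenario$pathway_id), esc(scenario$title)))
  entry_line <- function(id, names, type, reaction = NULL) {
    sprintf('  <entry id="%s" name="%s" type="%s"%s/>',
            esc(id), esc(paste(names, collapse = " ")), type,
            if (is.null(reaction)) ""
            else sprintf(' reaction="%s"', esc(reaction)))
  }
  # gene entries catalysing a reaction carry the reaction attribute
  enzyme_of <- character(0)
  if (!is.null(scenario$reactions) && nrow(scenario$reactions) > 0L) {
    rx <- scenario$reactions
    enzyme_of <- stats::setNames(rx$name, rx$enzyme)
  }
  for (id in names(scenario$genes)) {
    lines <- c(lines, entry_line(id, scenario$genes[[id]], "gene",
                                 reaction = if (id %in% names(enzyme_of))
                                   enzyme_of[[id]] else NULL))
  }
  for (id in names(scenario$orthologs)) {
    lines <- c(lines, entry_line(id, scenario$orthologs[[id]], "ortholog"))
  }
  for (id in names(scenario$compounds)) {
    lines <- c(lines, entry_line(id, scenario$compounds[[id]], "compound"))
  }
  for (id in names(scenario$maps)) {
    lines <- c(lines, entry_line(id, scenario$maps[[id]], "map"))
  }
  for (id in names(scenario$groups)) {
    comps <- paste(sprintf('    <component id="%s"/>',
                           esc(scenario$groups[[id]])), collapse = "\n")
    lines <- c(lines,
               sprintf('  <entry id="%s" name="undefined" type="group">',
                       esc(id)),
               comps, "  </entry>")
  }
  if (!is.null(scenario$relations) && nrow(scenario$relations) > 0L) {
    rl <- scenario$relations
    if (!"compound" %in% names(rl)) rl$compound <- NA_character_
    for (i in seq_len(nrow(rl))) {
      sub <- if (!is.na(rl$compound[i])) {
        sprintf('    <subtype name="compound" value="%s"/>',
                esc(rl$compound[i]))
      } else {
        sprintf('    <subtype name="%s" value="--"/>', esc(rl$subtype[i]))
      }
      lines <- c(lines,
                 sprintf('  <relation entry1="%s" entry2="%s" type="PPrel">',
                         esc(rl$source[i]), esc(rl$target[i])),
                 sub, "  </relation>")
    }
  }
  if (!is.null(scenario$reactions) && nrow(scenario$reactions) > 0L) {
    rx <- scenario$reactions
    for (i in seq_len(nrow(rx))) {
      lines <- c(lines,
                 sprintf('  <reaction id="%s" name="%s" type="%s">',
                         esc(rx$id[i]), esc(rx$name[i]),
                         if (isTRUE(rx$reversible[i])) "reversible"
                         else "irreversible"),
                 sprintf('    <substrate id="%s" name="sub"/>',
                         esc(rx$substrate[i])),
                 sprintf('    <product id="%s" name="prod"/>',
                         esc(rx$product[i])),
                 "  </reaction>")
    }
  }
  lines <- c(lines, "</pathway>")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Generate a randomized KGML scenario
#'
#' Draws a random pathway with the given entity counts: gene entries (a
#' small fraction carrying two identifiers), compounds, maps, optionally a
#' group complex, random direct relations between entries, a subset routed
#' through compounds, and a few reactions. The returned scenario carries an
#' `intended` attribute listing the entity inventory, used by round-trip
#' tests.
#'
#' @param seed Integer seed.
#' @param n_genes,n_compounds,n_maps Entity counts.
#' @param n_relations Number of relation elements.
#' @param n_reactions Number of reaction elements.
#' @param p_group Probability of including one two-gene group.
#' @param cyclic If `TRUE`, guarantee at least one directed gene cycle by
#'   adding a closing relation.
#' @param pathway_id Accession recorded in the document.
#' @return A [kgml_scenario()] with attribute `intended`.
#' @export
random_kgml_scenario <- function(seed, n_genes = 8L, n_compounds = 3L,
                                 n_maps = 1L, n_relations = 10L,
                                 n_reactions = 1L, p_group = 0.3,
                                 cyclic = NA,
                                 pathway_id = sprintf("path:syn%05d", seed %% 1e5)) {
  withr::with_seed(seed, {
    gene_ids <- sprintf("e%d", seq_len(n_genes))
    genes <- lapply(seq_len(n_genes), function(i) {
      if (stats::runif(1) < 0.15) sprintf("g%d g%d_b", i, i)
      else sprintf("g%d", i)
    })
    genes <- lapply(genes, function(x) strsplit(x, " ")[[1]])
    names(genes) <- gene_ids
    compounds <- as.list(sprintf("cpd:C%05d", seq_len(n_compounds)))
    names(compounds) <- sprintf("c%d", seq_len(n_compounds))
    maps <- if (n_maps > 0L) {
      stats::setNames(as.list(sprintf("path:map%05d", seq_len(n_maps))),
                      sprintf("m%d", seq_len(n_maps)))
    } else list()
    groups <- list()
    if (stats::runif(1) < p_group && n_genes >= 4L) {
      groups <- list(grp1 = sample(gene_ids, 2L))
    }
    node_ids <- c(gene_ids, names(compounds), names(maps), names(groups))
    subtypes <- c("activation", "inhibition", "expression",
                  "binding/association", "phosphorylation")
    rel <- NULL
    if (n_relations > 0L) {
      src <- sample(node_ids, n_relations, replace = TRUE)
      dst <- sample(node_ids, n_relations, replace = TRUE)
      keep <- src != dst
      rel <- data.frame(source = src[keep], target = dst[keep],
                        subtype = sample(subtypes, sum(keep), replace = TRUE),
                        compound = NA_character_,
                        stringsAsFactors = FALSE)
      # route ~1/4 of gene-gene relations through a random compound
      if (nrow(rel) > 0L && n_compounds > 0L) {
        via <- which(rel$source %in% gene_ids & rel$target %in% gene_ids &
                       stats::runif(nrow(rel)) < 0.25)
        rel$compound[via] <- sample(names(compounds), length(via),
                                    replace = TRUE)
      }
    }
    if (isTRUE(cyclic) && n_genes >= 3L) {
      cyc <- sample(gene_ids, 3L)
      rel <- rbind(rel, data.frame(
        source = cyc, target = cyc[c(2L, 3L, 1L)],
        subtype = "activation", compound = NA_character_,
        stringsAsFactors = FALSE))
    }
    rx <- NULL
    if (n_reactions > 0L && n_compounds >= 2L) {
      rx <- data.frame(
        id = sprintf("rn%d", seq_len(n_reactions)),
        name = sprintf("rn:R%05d", seq_len(n_reactions)),
        substrate = sample(names(compounds), n_reactions, replace = TRUE),
        product = sample(names(compounds), n_reactions, replace = TRUE),
        enzyme = sample(gene_ids, n_reactions, replace = TRUE),
        reversible = stats::runif(n_reactions) < 0.5,
        stringsAsFactors = FALSE)
      rx <- rx[rx$substrate != rx$product, , drop = FALSE]
      if (nrow(rx) == 0L) rx <- NULL
    }
    sc <- kgml_scenario(genes = genes, compounds = compounds, maps = maps,
                        groups = groups, relations = rel, reactions = rx,
                        pathway_id = pathway_id,
                        title = sprintf("synthetic pathway %d", seed))
    n_links <- 0L
    if (!is.null(rel) && nrow(rel) > 0L) {
      # compound-routed relations are written with the compound subtype in
      # place of the original label, so they always emit exactly two links
      per <- ifelse(!is.na(rel$compound), 2L,
                    ifelse(rel$subtype == "binding/association", 2L, 1L))
      n_links <- n_links + sum(per)
    }
    if (!is.null(rx)) {
      n_links <- n_links + sum(2L * (1L + rx$reversible))
    }
    attr(sc, "intended") <- list(
      gene_names = sort_lex(unique(unlist(genes))),
      compound_names = sort_lex(unique(unlist(compounds))),
      map_names = sort_lex(unique(unlist(maps))),
      n_links = n_links)
    sc
  })
}

#' Write a directory of synthetic KGML fixture files
#'
#' @param dir Output directory (created if needed).
#' @param n Number of pathway files.
#' @param seed Master seed; file `i` uses a sub-seed derived from it.
#' @param cyclic_fraction Fraction of fixtures forced to contain a gene
#'   cycle.
#' @return Invisibly, the written file paths.
#' @export
write_kgml_fixtures <- function(dir, n = 10L, seed = 1L,
                                cyclic_fraction = 0.6) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(n)
  for (i in seq_len(n)) {
    sc <- random_kgml_scenario(
      seed = derive_seed(seed, i),
      n_genes = 6L + (i %% 7L),
      cyclic = i <= ceiling(n * cyclic_fraction),
      pathway_id = sprintf("path:syn%05d", i))
    paths[i] <- file.path(dir, sprintf("syn%05d.xml", i))
    writeLines(kgml_build(sc), paths[i], sep = "")
  }
  invisible(paths)
}

#' Generate a random gene network
#'
#' Draws `n_edges` distinct ordered pairs (no self-loops) over `n_genes`
#' genes. Used throughout the test-suite and by the benchmark properties.
#'
#' @param n_genes Number of genes.
#' @param n_edges Number of directed edges.
#' @param seed Integer seed.
#' @param signed If `TRUE`, edges get random activating/inhibiting signs;
#'   otherwise all unknown.
#' @param require_cycle If `TRUE`, redraw (bounded) until the network is
#'   cyclic, closing a random 2-path if needed.
#' @return A [gene_network].
#' @export
random_gene_network <- function(n_genes, n_edges, seed, signed = FALSE,
                                require_cycle = FALSE) {
  stopifnot(n_edges <= n_genes * (n_genes - 1L))
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(n_genes))
    pairs <- expand.grid(from = genes, to = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    idx <- sample(nrow(pairs), n_edges)
    edges <- pairs[idx, , drop = FALSE]
    edges$sign <- if (signed) {
      sample(c("activating", "inhibiting"), n_edges, replace = TRUE)
    } else rep("unknown", n_edges)
    g <- gene_network(genes, edges)
    if (require_cycle && !has_cycle(g) && n_edges > 0L) {
      # close a cycle along an existing edge's reverse
      e1 <- g$edges[sample(nrow(g$edges), 1L), ]
      extra <- tibble::tibble(from = e1$to, to = e1$from, sign = e1$sign)
      g <- gene_network(genes, dplyr::bind_rows(g$edges, extra))
    }
    g
  })
}

#' Generate a random regulatory DAG as a true simulation topology
#'
#' Draws an acyclic network shaped like a biological regulatory network:
#' a random gene ordering with forward edges sampled under an in-degree
#' cap (biological transcriptional networks, and the source networks the
#' simulator emulates, rarely give a gene more than a few regulators).
#' Used as the ground-truth topology in simulation studies; the null
#' model for scoring remains the unconstrained [sample_random_dag()].
#'
#' @param n_genes Number of genes.
#' @param n_edges Number of edges; defaults to `round(1.3 * n_genes)`.
#' @param seed Integer seed.
#' @param max_in_degree In-degree cap; default 3.
#' @param signed Random activating/inhibiting signs if `TRUE`.
#' @return An acyclic [gene_network].
#' @export
random_regulatory_dag <- function(n_genes, n_edges = round(1.3 * n_genes),
                                  seed = 1L, max_in_degree = 3L,
                                  signed = TRUE) {
  stopifnot(n_edges <= n_genes * (n_genes - 1L) / 2L)
  genes <- sprintf("g%02d", seq_len(n_genes))
  withr::with_seed(seed, {
    perm <- sample(genes)
    pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
    pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
    indeg <- stats::setNames(integer(n_genes), genes)
    from <- character(0); to <- character(0)
    for (i in seq_len(nrow(pairs))) {
      if (length(from) == n_edges) break
      tg <- perm[pairs[i, 2L]]
      if (indeg[[tg]] >= max_in_degree) next
      from <- c(from, perm[pairs[i, 1L]])
      to <- c(to, tg)
      indeg[[tg]] <- indeg[[tg]] + 1L
    }
    sgn <- if (signed) sample(c("activating", "inhibiting"),
                              length(from), replace = TRUE)
           else rep("unknown", length(from))
  })
  gene_network(genes, tibble::tibble(from = from, to = to, sign = sgn))
}

#' Generate a random DAG to use as a simulation topology
#'
#' Convenience wrapper around [sample_random_dag()] that names genes
#' `g01..gNN`.
#'
#' @param n_genes,n_edges Node and edge counts.
#' @param seed Integer seed.
#' @param signed Random activating/inhibiting signs if `TRUE`.
#' @return An acyclic [gene_network].
#' @export
random_dag_network <- function(n_genes, n_edges, seed, signed = TRUE) {
  g <- sample_random_dag(sprintf("g%02d", seq_len(n_genes)), n_edges, seed)
  if (signed && nrow(g$edges) > 0L) {
    withr::with_seed(derive_seed(seed, "signs"), {
      g$edges$sign <- sample(c("activating", "inhibiting"),
                             nrow(g$edges), replace = TRUE)
    })
  }
  g
}
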