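#' Parse a KGML pathway document
#'
#' Reads a KGML (KEGG Markup Language) XML document and returns a typed
#' pathway model: entries (genes, orthologs, compounds, maps, groups,
#' enzymes), relation-derived links and reaction-derived links.
#'
#' Link semantics:
#' * a relation whose subtype names a compound entry is decomposed into
#'   `entry1 -> compound` and `compound -> entry2`, making the compound an
#'   explicit traversable intermediate (this is what lets indirect gene-gene
#'   paths through compounds be recovered later); the regulatory sign rides
#'   on the `compound -> entry2` hop, the first hop is neutral;
#' * binding/association subtypes are undirected in KGML and emit links in
#'   both directions;
#' * a reaction emits `substrate -> enzyme-entry` and
#'   `enzyme-entry -> product` links for every entry catalysing it (matched
#'   by the entry's `reaction` attribute, falling back to the reaction id);
#'   reversible reactions also emit the mirrored links.
#'
#' Relations that reference a missing entry id are skipped with a warning;
#' unknown entry types are kept with kind `"other"` and a warning. Malformed
#' XML raises the parser's error, which names the offending line.
#'
#' @param document Path to a KGML file, or the XML text itself.
#' @return A `pathway_model`: list with `pathway_id`, `title`, `entries`
#'   (tibble: `entry_id`, `kind`, `names` list-column, `members`
#'   list-column) and `links` (tibble: `source`, `target`, `origin`,
#'   `subtype`, `sign`).
#' @examples
#' doc <- kgml_build(kgml_scenario(
#'   genes = list(e1 = "hsa:1", e2 = "hsa:2"),
#'   relations = data.frame(source = "e1", target = "e2",
#'                          subtype = "activation")))
#' parse_kgml(doc)
#' @export
parse_kgml <- function(document) {
  doc <- if (length(document) == 1L && !grepl("<", document, fixed = TRUE)) {
    xml2::read_xml(document)  # a path
  } else {
    xml2::read_xml(paste(document, collapse = "\n"))
  }
  root <- xml2::xml_name(doc)
  if (root != "pathway") {
    stop("not a KGML document: root element is <", root, ">", call. = FALSE)
  }
  pathway_id <- xml2::xml_attr(doc, "name")
  title <- xml2::xml_attr(doc, "title")

  known_kinds <- c("gene", "ortholog", "compound", "map", "group", "enzyme")
  entry_nodes <- xml2::xml_find_all(doc, "./entry")
  entry_id <- xml2::xml_attr(entry_nodes, "id")
  entry_type <- xml2::xml_attr(entry_nodes, "type")
  kind <- ifelse(entry_type %in% known_kinds, entry_type, "other")
  unknown <- setdiff(unique(entry_type), c(known_kinds, NA))
  if (length(unknown) > 0L) {
    warning("unknown KGML entry type(s) kept as 'other': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  entry_names <- lapply(entry_nodes, function(e) {
    nm <- xml2::xml_attr(e, "name")
    if (is.na(nm) || nm == "") character(0)
    else strsplit(nm, " ", fixed = TRUE)[[1]]
  })
  members <- lapply(entry_nodes, function(e) {
    xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id")
  })
  entries <- tibble::tibble(entry_id = entry_id, kind = kind,
                            names = entry_names, members = members)
  if (anyDuplicated(entries$entry_id)) {
    stop("duplicate entry ids in KGML document", call. = FALSE)
  }
  reaction_attr <- stats::setNames(xml2::xml_attr(entry_nodes, "reaction"),
                                   entry_id)

  links <- list()
  add_link <- function(source, target, origin, subtype, sign) {
    links[[length(links) + 1L]] <<-
      tibble::tibble(source = source, target = target, origin = origin,
                     subtype = subtype, sign = sign)
  }

  subtype_sign <- function(names) {
    if (any(names %in% c("activation", "expression"))) "activating"
    else if (any(names %in% c("inhibition", "repression"))) "inhibiting"
    else "unknown"
  }

  for (rel in xml2::xml_find_all(doc, "./relation")) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    st_nodes <- xml2::xml_find_all(rel, "./subtype")
    st_names <- xml2::xml_attr(st_nodes, "name")
    st_values <- xml2::xml_attr(st_nodes, "value")
    if (!all(c(e1, e2) %in% entries$entry_id)) {
      warning(sprintf("relation %s->%s references a missing entry; skipped",
                      e1, e2), call. = FALSE)
      next
    }
    sgn <- subtype_sign(st_names)
    label <- if (length(st_names)) paste(st_names, collapse = "+") else ""
    cpd_idx <- which(st_names %in% c("compound", "hidden compound"))
    cpd_ids <- st_values[cpd_idx]
    cpd_ids <- cpd_ids[cpd_ids %in% entries$entry_id]
    if (length(cpd_idx) > 0L && length(cpd_ids) == 0L) {
      warning(sprintf(
        "relation %s->%s: compound subtype references a missing entry; skipped",
        e1, e2), call. = FALSE)
      next
    }
    undirected <- any(st_names %in% c("binding/association", "binding",
                                      "association"))
    if (length(cpd_ids) > 0L) {
      for (cid in cpd_ids) {
        add_link(e1, cid, "relation", label, "activating")
        add_link(cid, e2, "relation", label, sgn)
        if (undirected) {
          add_link(e2, cid, "relation", label, "activating")
          add_link(cid, e1, "relation", label, sgn)
        }
      }
    } else {
      add_link(e1, e2, "relation", label, sgn)
      if (undirected) add_link(e2, e1, "relation", label, sgn)
    }
  }

  for (rxn in xml2::xml_find_all(doc, "./reaction")) {
    rxn_id <- xml2::xml_attr(rxn, "id")
    rxn_name <- xml2::xml_attr(rxn, "name")
    reversible <- identical(xml2::xml_attr(rxn, "type"), "reversible")
    subs <- xml2::xml_attr(xml2::xml_find_all(rxn, "./substrate"), "id")
    prods <- xml2::xml_attr(xml2::xml_find_all(rxn, "./product"), "id")
    catalysts <- names(reaction_attr)[
      !is.na(reaction_attr) &
        vapply(strsplit(reaction_attr, " ", fixed = TRUE),
               function(r) any(r %in% c(rxn_name, rxn_id)), logical(1))]
    if (length(catalysts) == 0L && !is.na(rxn_id) &&
        rxn_id %in% entries$entry_id) {
      catalysts <- rxn_id
    }
    endpoints <- c(subs, prods)
    if (!all(endpoints %in% entries$entry_id) || length(catalysts) == 0L) {
      warning(sprintf("reaction %s references missing entries; skipped",
                      rxn_name %||% rxn_id), call. = FALSE)
      next
    }
    for (enz in catalysts) {
      for (s in subs) {
        add_link(s, enz, "reaction_substrate", "reaction", "unknown")
        if (reversible) add_link(enz, s, "reaction_product", "reaction",
                                 "unknown")
      }
      for (p in prods) {
        add_link(enz, p, "reaction_product", "reaction", "unknown")
        if (reversible) add_link(p, enz, "reaction_substrate", "reaction",
                                 "unknown")
      }
    }
  }

  links <- if (length(links)) dplyr::bind_rows(links) else
    tibble::tibble(source = character(), target = character(),
                   origin = character(), subtype = character(),
                   sign = character())
  structure(list(pathway_id = pathway_id, title = title,
                 entries = entries, links = links),
            class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("<pathway_model> %s (%s): %d entries, %d links\n",
              x$pathway_id %||% "?", x$title %||% "?",
              nrow(x$entries), nrow(x$links)))
  print(table(x$entries$kind))
  invisible(x)
}

#' Build the heterogeneous pathway graph from a parsed model
#'
#' Flattens a `pathway_model` into a directed graph over concrete entities:
#' group entries (complexes) are dissolved, with every link to or from the
#' group lifted to each member, and multi-identifier entries expand to one
#' node per KEGG identifier, all inheriting the entry's links. Duplicate
#' directed edges merge; a sign conflict collapses to `"unknown"`;
#' self-edges arising from the expansion are dropped.
#'
#' @param model A `pathway_model` from [parse_kgml()].
#' @param orthologs_as_genes Treat ortholog (KO) entries as gene-kind nodes.
#'   Default `FALSE`: reference-pathway ortholog entries become
#'   non-gene (`"other"`) nodes, i.e. traversable intermediates.
#' @return A `hetero_graph`: list with `nodes` (tibble: `name`, `kind`) and
#'   `edges` (tibble: `from`, `to`, `sign`).
#' @export
build_hetero_graph <- function(model, orthologs_as_genes = FALSE) {
  stopifnot(inherits(model, "pathway_model"))
  entries <- model$entries

  node_kind <- function(kind) {
    if (kind == "gene") "gene"
    else if (kind == "ortholog") {
      if (orthologs_as_genes) "gene" else "other"
    } else kind
  }

  # entry_id -> expanded node names (groups flatten recursively).
  expand_entry <- function(id, seen = character()) {
    if (id %in% seen) return(character(0))  # defensive: cyclic groups
    row <- which(entries$entry_id == id)
    if (length(row) == 0L) return(character(0))
    if (entries$kind[row] == "group") {
      unlist(lapply(entries$members[[row]], expand_entry,
                    seen = c(seen, id)))
    } else {
      entries$names[[row]]
    }
  }
  expansion <- lapply(entries$entry_id, expand_entry)
  names(expansion) <- entries$entry_id

  nodes <- list()
  for (i in seq_len(nrow(entries))) {
    if (entries$kind[i] == "group") next
    nm <- entries$names[[i]]
    if (length(nm) == 0L) next
    nodes[[length(nodes) + 1L]] <-
      tibble::tibble(name = nm, kind = node_kind(entries$kind[i]))
  }
  nodes <- if (length(nodes)) dplyr::bind_rows(nodes) else
    tibble::tibble(name = character(), kind = character())
  # group members appear through their own entries; dedupe by name,
  # preferring the gene kind on the rare conflict
  nodes <- nodes |>
    dplyr::arrange(.data$name, .data$kind != "gene") |>
    dplyr::distinct(.data$name, .keep_all = TRUE)
  nodes <- nodes[order_lex(nodes$name), ]

  edges <- list()
  if (nrow(model$links) > 0L) {
    for (i in seq_len(nrow(model$links))) {
      src <- expansion[[model$links$source[i]]]
      dst <- expansion[[model$links$target[i]]]
      if (length(src) == 0L || length(dst) == 0L) next
      grid <- expand.grid(from = src, to = dst, stringsAsFactors = FALSE)
      grid$sign <- model$links$sign[i]
      edges[[length(edges) + 1L]] <- grid
    }
  }
  edges <- if (length(edges)) tibble::as_tibble(dplyr::bind_rows(edges)) else
    tibble::tibble(from = character(), to = character(), sign = character())
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges) > 0L) {
    edges <- edges |>
      dplyr::summarise(
        sign = if (dplyr::n_distinct(.data$sign) == 1L) .data$sign[1L]
               else "unknown",
        .by = c("from", "to"))
    edges <- edges[order(edges$from, edges$to, method = "radix"), ]
  }
  structure(list(nodes = nodes, edges = edges), class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("<hetero_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$kind))
  invisible(x)
}

# Construct a hetero_graph directly (used by tests and the collapse oracle).
hetero_graph <- function(nodes, edges = NULL) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("name", "kind") %in% names(nodes)))
  nodes <- nodes[order_lex(nodes$name), c("name", "kind")]
  if (anyDuplicated(nodes$name)) stop("duplicate node names", call. = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(),
                            sign = character())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!"sign" %in% names(edges)) edges$sign <- "unknown"
    stopifnot(all(edges$from %in% nodes$name), all(edges$to %in% nodes$name))
    edges <- edges |>
      dplyr::summarise(
        sign = if (dplyr::n_distinct(.data$sign) == 1L) .data$sign[1L]
               else "unknown",
        .by = c("from", "to"))
    edges <- edges[order(edges$from, edges$to, method = "radix"),
                   c("from", "to", "sign")]
  }
  structure(list(nodes = nodes, edges = edges), class = "hetero_graph")
}
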