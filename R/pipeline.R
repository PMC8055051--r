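#' Configuration for a pipeline run
#'
#' Collects every tunable of the end-to-end workflow, with all seeds
#' explicit so two runs with the same configuration are byte-identical.
#'
#' @param methods Cycle-removal methods to apply.
#' @param seed Master seed; per-pathway sub-seeds for the simulator, the
#'   TrueSkill shuffles and the random-DAG nulls are derived from it.
#' @param n_samples Expression samples to simulate per cyclic pathway.
#' @param n_random_dags Random DAGs per method DAG (1000 is the full-scale
#'   default; tests and examples run far fewer).
#' @param min_nonisolated Minimum non-isolated gene count; smaller networks
#'   are recorded as skipped.
#' @param noise_sd Simulator measurement-noise standard deviation.
#' @param discretize_levels Bins for [discretize()].
#' @param formats Network serialization formats to write.
#' @return A `run_config` list.
#' @export
run_config <- function(methods = c("dfs", "mfas", "pr", "en"),
                       seed = 1L,
                       n_samples = 100L,
                       n_random_dags = 1000L,
                       min_nonisolated = 6L,
                       noise_sd = 0.05,
                       discretize_levels = 3L,
                       formats = c("sif", "adjacency")) {
  methods <- match.arg(methods, c("dfs", "mfas", "pr", "en"),
                       several.ok = TRUE)
  formats <- match.arg(formats, c("sif", "adjacency"), several.ok = TRUE)
  structure(list(methods = methods, seed = as.integer(seed),
                 n_samples = as.integer(n_samples),
                 n_random_dags = as.integer(n_random_dags),
                 min_nonisolated = as.integer(min_nonisolated),
                 noise_sd = noise_sd,
                 discretize_levels = as.integer(discretize_levels),
                 formats = formats),
            class = "run_config")
}

write_network_files <- function(g, out_dir, stem, formats) {
  ext <- c(sif = "sif", adjacency = "adj.tsv")
  for (f in formats) {
    cat(serialize_network(g, f),
        file = file.path(out_dir, paste0(stem, ".", ext[[f]])))
  }
}

#' Run the full workflow on one KGML file
#'
#' Parses the pathway, collapses it to the gene-only network and writes the
#' network files. Networks below the non-isolated threshold are flagged
#' skipped (they still get their network files). Cyclic networks go through
#' the full comparison: the four DAGs, the removed-edge sidecars, a
#' simulated expression dataset fitting the network topology, its
#' 3-level discretization, BIC scores for each DAG and for
#' `n_random_dags` node/edge-matched random DAGs per method, and the rank
#' statistics. Acyclic networks emit DAG files identical to the network and
#' no scores.
#'
#' @param kgml_path Path to a KGML file.
#' @param out_dir Output directory for artifact files (created if needed).
#' @param config A [run_config()].
#' @return A one-row tibble (the benchmark record): pathway id/name, node
#'   and edge counts, cyclic flag, per-method `removed_*`, `removal_rank_*`,
#'   `bic_*`, `score_rank_*`, `randoms_beating_*`, and a `status` column
#'   (`"ok"`, `"skipped"`).
#' @export
run_pathway <- function(kgml_path, out_dir, config = run_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- parse_kgml(kgml_path)
  h <- build_hetero_graph(model)
  net <- collapse_to_gene_network(h)
  stem <- gsub("[^A-Za-z0-9_.-]", "_", model$pathway_id %||% "pathway")
  write_network_files(net, out_dir, paste0(stem, ".network"),
                      config$formats)

  methods <- config$methods
  rec <- tibble::tibble(
    pathway_id = model$pathway_id %||% NA_character_,
    pathway_name = model$title %||% NA_character_,
    n_nodes = length(net$genes),
    n_edges = nrow(net$edges),
    n_nonisolated = nonisolated_count(net),
    cyclic = has_cycle(net),
    status = "ok")
  for (m in methods) {
    rec[[paste0("removed_", m)]] <- NA_integer_
    rec[[paste0("removal_rank_", m)]] <- NA_integer_
    rec[[paste0("bic_", m)]] <- NA_real_
    rec[[paste0("score_rank_", m)]] <- NA_integer_
    rec[[paste0("randoms_beating_", m)]] <- NA_integer_
  }
  rec$n_random_dags <- config$n_random_dags

  if (rec$n_nonisolated < config$min_nonisolated) {
    rec$status <- "skipped"
    return(rec)
  }

  path_seed <- derive_seed(config$seed, rec$pathway_id)
  dags <- lapply(stats::setNames(methods, methods), function(m) {
    remove_cycles(net, m, seed = derive_seed(path_seed, m))
  })
  for (m in methods) {
    write_network_files(dags[[m]]$dag, out_dir,
                        sprintf("%s.dag_%s", stem, m), config$formats)
    sidecar <- dags[[m]]$removed
    utils::write.table(
      data.frame(source = sidecar$from, target = sidecar$to,
                 method = rep(m, nrow(sidecar))),
      file.path(out_dir, sprintf("%s.dag_%s.removed.tsv", stem, m)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rec[[paste0("removed_", m)]] <- nrow(sidecar)
  }
  removal_ranks <- dense_rank_asc(
    vapply(dags, function(d) nrow(d$removed), numeric(1)))
  for (m in methods) {
    rec[[paste0("removal_rank_", m)]] <- removal_ranks[[m]]
  }

  if (!rec$cyclic) return(rec)

  km <- assign_kinetics(net, seed = derive_seed(path_seed, "kinetics"))
  expr <- generate_expression(km, n_samples = config$n_samples,
                              noise_sd = config$noise_sd,
                              seed = derive_seed(path_seed, "expression"))
  if (mean(expr$converged) < 0.5) {
    warning(sprintf("%s: %.0f%% of simulated samples did not converge",
                    rec$pathway_id, 100 * (1 - mean(expr$converged))),
            call. = FALSE)
  }
  expr <- discretize(expr, levels = config$discretize_levels)
  write_expression(expr, file.path(out_dir,
                                   paste0(stem, ".expression.tsv")))

  bics <- vapply(dags, function(d) bic_score(d$dag, expr), numeric(1))
  score_ranks <- if (setequal(methods, c("dfs", "mfas", "pr", "en"))) {
    rank_scores(bics)
  } else {
    vals <- sort(unique(bics), decreasing = TRUE)
    stats::setNames(match(bics, vals), names(bics))
  }
  score_rows <- list()
  for (m in methods) {
    d <- dags[[m]]
    rand_scores <- vapply(seq_len(config$n_random_dags), function(k) {
      rd <- sample_random_dag(d$dag$genes, nrow(d$dag$edges),
                              seed = derive_seed(path_seed,
                                                 paste0("rand_", m, "_", k)))
      bic_score(rd, expr)
    }, numeric(1))
    rec[[paste0("bic_", m)]] <- bics[[m]]
    rec[[paste0("score_rank_", m)]] <- score_ranks[[m]]
    rec[[paste0("randoms_beating_", m)]] <-
      rank_against_randoms(bics[[m]], rand_scores)
    score_rows[[m]] <- data.frame(
      method = m, bic = bics[[m]],
      rank_among_methods = score_ranks[[m]],
      randoms_beating = rec[[paste0("randoms_beating_", m)]],
      R = config$n_random_dags)
  }
  utils::write.table(do.call(rbind, score_rows),
                     file.path(out_dir, paste0(stem, ".scores.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec
}

#' Run the benchmark over a directory of KGML files
#'
#' Applies [run_pathway()] to every `*.xml`/`*.kgml` file, collects the
#' per-pathway records into the benchmark table, writes it as TSV together
#' with a plain-text run manifest (all configuration values and seeds),
#' and attaches the per-method summary (mean edges removed, mean removal
#' rank, mean score rank, mean randoms beating) as attribute `"summary"`.
#' A pathway that fails to parse is logged and recorded as a failed row;
#' the run continues.
#'
#' @param kgml_dir Directory containing at least one KGML file.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return The benchmark tibble (class `kegg2net_benchmark`), one row per
#'   pathway, with attribute `summary`.
#' @export
run_benchmark <- function(kgml_dir, out_dir, config = run_config()) {
  files <- sort_lex(list.files(kgml_dir, pattern = "\\.(xml|kgml)$",
                               full.names = TRUE))
  if (length(files) == 0L) {
    stop("no KGML files (*.xml, *.kgml) in ", kgml_dir, call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- lapply(files, function(f) {
    tryCatch(run_pathway(f, out_dir, config),
             error = function(e) {
               message("pathway ", basename(f), " failed: ",
                       conditionMessage(e))
               tibble::tibble(pathway_id = basename(f),
                              pathway_name = NA_character_,
                              n_nodes = NA_integer_, n_edges = NA_integer_,
                              n_nonisolated = NA_integer_, cyclic = NA,
                              status = "failed")
             })
  })
  tab <- dplyr::bind_rows(rows)
  summary_tab <- benchmark_summary(tab, config$methods)
  utils::write.table(tab, file.path(out_dir, "benchmark.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary_tab, file.path(out_dir, "benchmark_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(
    sprintf("kegg2net_version=%s",
            as.character(utils::packageVersion("kegg2net"))),
    sprintf("n_pathways=%d", nrow(tab)),
    sprintf("methods=%s", paste(config$methods, collapse = ",")),
    sprintf("seed=%d", config$seed),
    sprintf("n_samples=%d", config$n_samples),
    sprintf("n_random_dags=%d", config$n_random_dags),
    sprintf("min_nonisolated=%d", config$min_nonisolated),
    sprintf("noise_sd=%g", config$noise_sd),
    sprintf("discretize_levels=%d", config$discretize_levels),
    sprintf("formats=%s", paste(config$formats, collapse = ",")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  attr(tab, "summary") <- summary_tab
  class(tab) <- c("kegg2net_benchmark", class(tab))
  tab
}

# Per-method summary over the scored (cyclic, ok) rows: the four panels of
# the comparison — mean edges removed, mean removal rank, mean score rank,
# mean count of random DAGs beating the method DAG.
benchmark_summary <- function(tab, methods = c("dfs", "mfas", "pr", "en")) {
  ok <- tab[!is.na(tab$cyclic) & tab$status == "ok", , drop = FALSE]
  cyc <- ok[ok$cyclic, , drop = FALSE]
  rows <- lapply(methods, function(m) {
    tibble::tibble(
      method = m,
      n_networks = nrow(ok),
      n_cyclic = nrow(cyc),
      mean_edges_removed = if (nrow(ok)) mean(ok[[paste0("removed_", m)]],
                                              na.rm = TRUE) else NA_real_,
      mean_removal_rank = if (nrow(ok)) mean(ok[[paste0("removal_rank_", m)]],
                                             na.rm = TRUE) else NA_real_,
      mean_score_rank = if (nrow(cyc)) mean(cyc[[paste0("score_rank_", m)]],
                                            na.rm = TRUE) else NA_real_,
      mean_randoms_beating = if (nrow(cyc))
        mean(cyc[[paste0("randoms_beating_", m)]], na.rm = TRUE)
        else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Convert one KGML file to its network and DAGs (no benchmark)
#'
#' The lightweight path of the tool: parse, collapse, write the network
#' files and (if cyclic) the four DAG files, skipping simulation and
#' scoring.
#'
#' @param kgml_path Path to a KGML file.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return Invisibly, a list with the collapsed `network` and the
#'   `dag_result`s.
#' @export
convert_pathway <- function(kgml_path, out_dir, config = run_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- parse_kgml(kgml_path)
  net <- collapse_to_gene_network(build_hetero_graph(model))
  stem <- gsub("[^A-Za-z0-9_.-]", "_", model$pathway_id %||% "pathway")
  write_network_files(net, out_dir, paste0(stem, ".network"),
                      config$formats)
  path_seed <- derive_seed(config$seed, model$pathway_id %||% "pathway")
  dags <- lapply(stats::setNames(config$methods, config$methods),
                 function(m) {
                   d <- remove_cycles(net, m, seed = derive_seed(path_seed, m))
                   write_network_files(d$dag, out_dir,
                                       sprintf("%s.dag_%s", stem, m),
                                       config$formats)
                   utils::write.table(
                     data.frame(source = d$removed$from,
                                target = d$removed$to,
                                method = rep(m, nrow(d$removed))),
                     file.path(out_dir,
                               sprintf("%s.dag_%s.removed.tsv", stem, m)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
                   d
                 })
  invisible(list(network = net, dags = dags))
}
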