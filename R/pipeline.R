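# Orchestration of the four stages over files on disk: batch comparison,
# weight training, pathway ranking, and fixture simulation. These functions
# are the programmatic surface the numbered analysis scripts drive; every
# report is tab-delimited with a '#'-prefixed header block recording
# configuration and package version for provenance.

.report_header <- function(stage, extra = character(0)) {
  c(sprintf("# radialsim %s | stage: %s | %s",
            as.character(utils::packageVersion("radialsim")), stage,
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("# ", extra))
}

.write_report <- function(df, path, stage, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.report_header(stage, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text pipeline configuration
#'
#' YAML key/value file with optional keys `breakpoints` (shell boundaries),
#' `weights` (path to a weights file, otherwise the packaged trained
#' weights), `mode` (`union`/`literal`), `sink`, `seed`, `outdir`. Missing
#' keys fall back to the packaged defaults, which reproduce the published
#' boundaries and weights exactly.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return List with `scheme`, `weights`, `mode`, `sink`, `seed`, `outdir`.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  scheme <- if (!is.null(cfg$breakpoints)) layer_scheme(cfg$breakpoints) else default_layer_scheme()
  weights <- if (!is.null(cfg$weights)) read_weights(cfg$weights) else table1_weights()
  mode <- if (!is.null(cfg$mode)) match.arg(cfg$mode, c("union", "literal")) else "union"
  list(scheme = scheme, weights = weights, mode = mode,
       sink = if (!is.null(cfg$sink)) cfg$sink else "Cell proliferation",
       seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L,
       outdir = if (!is.null(cfg$outdir)) cfg$outdir else ".")
}

#' Batch comparison of a query structure against targets
#'
#' Computes the nine-parameter vector and overall weighted similarity of the
#' query against every target and returns one row per target, sorted by
#' descending overall score. Columns follow the published reference-table
#' layout: atom count, amino-acid count, amino-acid types, C, N, O, S
#' position, P position, spatial structure (density), then the overall
#' score. Unreadable targets are skipped with their error recorded;
#' the batch continues and the failures are attached as
#' `attr(, "errors")` and raised as a warning at the end.
#'
#' @param query Path to the query PDB file, or a [protein_structure].
#' @param targets Character vector of target PDB paths, or a named list of
#'   [protein_structure] objects.
#' @param weights Nine combination weights (default: packaged trained
#'   weights).
#' @param scheme A [layer_scheme].
#' @param out Optional path for the TSV report.
#' @return `data.frame` with columns `target`, `atoms`, `amino_acids`,
#'   `amino_acid_types`, `C`, `N`, `O`, `S_position`, `P_position`,
#'   `spatial_structure`, `overall`.
#' @export
run_compare <- function(query, targets, weights = table1_weights(),
                        scheme = default_layer_scheme(), out = NULL) {
  q <- if (inherits(query, "protein_structure")) query else read_structure(query)
  if (length(targets) < 1L) stop("at least one target structure is required")
  nm <- if (!is.null(names(targets)) && all(nzchar(names(targets)))) {
    names(targets)
  } else if (is.character(targets)) {
    sub("\\.[^.]*$", "", basename(targets))
  } else {
    vapply(targets, function(t) if (inherits(t, "protein_structure")) t$id else "?", character(1))
  }
  rows <- list()
  errors <- character(0)
  for (i in seq_along(targets)) {
    res <- tryCatch({
      t <- targets[[i]]
      if (!inherits(t, "protein_structure")) t <- read_structure(t)
      v <- parameter_vector(q, t, scheme)
      c(atoms = unname(v["s2"]), amino_acids = unname(v["s3"]),
        amino_acid_types = unname(v["s4"]), C = unname(v["s5"]),
        N = unname(v["s6"]), O = unname(v["s7"]),
        S_position = unname(v["s9"]), P_position = unname(v["s8"]),
        spatial_structure = unname(v["s1"]),
        overall = overall_similarity(v, weights))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", nm[i], conditionMessage(res)))
    } else {
      rows[[nm[i]]] <- res
    }
  }
  if (length(rows) == 0L) stop("every target failed: ", paste(errors, collapse = "; "))
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(target = names(rows), df, stringsAsFactors = FALSE)
  df <- df[order(-df$overall, df$target), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(out)) {
    .write_report(df, out, "compare",
                  sprintf("query: %s | weights: %s", q$id,
                          paste(format(weights, digits = 4), collapse = ",")))
  }
  if (length(errors) > 0L) {
    warning("some targets failed: ", paste(errors, collapse = "; "))
  }
  attr(df, "errors") <- errors
  df
}

#' Train weights from a table on disk
#'
#' Reads a 10-column training table, fits the nine weights by gradient
#' descent, and optionally writes them as a weights file consumable by
#' [run_compare()].
#'
#' @param table_path Path to a TSV training table (`S1` ... `S9`, `S`).
#' @param cfg A [training_config()].
#' @param out Optional output path for the weights file.
#' @return The [train_weights()] result.
#' @export
run_train <- function(table_path, cfg = training_config(), out = NULL) {
  tab <- read_training_table(table_path)
  fit <- train_weights(tab, cfg)
  if (!is.null(out) && !is.null(fit$weights)) write_weights(fit$weights, out)
  fit
}

#' Rank pathways of a signed network read from disk
#'
#' Reads a signed edge list and a priors table, builds and validates the
#' DAG, clamps priors into `[0, 1]`, propagates node probabilities in the
#' requested mode, and ranks every source-to-sink pathway. With an output
#' directory, writes `pathway_ranking.tsv` (top pathway first) and
#' `node_probabilities.tsv`, both carrying the propagation mode in their
#' header block.
#'
#' @param edges_path Path to the edge list (`source`, `target`, `sign`).
#' @param priors_path Path to the priors table (`node`, `score`).
#' @param sink Sink node name.
#' @param mode Propagation mode, `"union"` (default) or `"literal"`.
#' @param out_dir Optional output directory.
#' @return List with `network`, `node_probabilities`, `ranking`.
#' @export
run_pathway <- function(edges_path, priors_path, sink = "Cell proliferation",
                        mode = c("union", "literal"), out_dir = NULL) {
  mode <- match.arg(mode)
  edges <- read_edge_list(edges_path)
  scores <- read_priors(priors_path)
  net <- build_network(edges, sink = sink)
  net <- set_priors(net, scores)
  probs <- propagate(net, mode = mode)
  ranking <- rank_pathways(net)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_report(ranking, file.path(out_dir, "pathway_ranking.tsv"), "pathway",
                  sprintf("mode: %s | sink: %s", mode, sink))
    .write_report(data.frame(node = names(probs), probability = unname(probs)),
                  file.path(out_dir, "node_probabilities.tsv"), "pathway",
                  sprintf("mode: %s | sink: %s", mode, sink))
  }
  list(network = net, node_probabilities = probs, ranking = ranking)
}

#' Simulate a complete fixture set
#'
#' Writes, under one directory: a query and several target structures in
#' PDB format, a labelled training table generated from the packaged
#' weights, a signed network edge list and priors with a planted dominant
#' pathway, and a `manifest.json` recording the ground truth of every
#' artifact (planned shell counts, compositions, generating weights,
#' planted pathway). Byte-identical across runs with the same seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-artifact seeds derive from it.
#' @param n_targets Number of target structures.
#' @param n_pairs Training-table size.
#' @param noise_sd Training label noise.
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, n_targets = 3L, n_pairs = 100L,
                         noise_sd = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  qspec <- structure_spec(n_atoms = 600L, seed = seed)
  query <- make_structure(qspec, id = "query",
                          path = file.path(out_dir, "query.pdb"))
  targets <- list()
  for (i in seq_len(n_targets)) {
    tspec <- structure_spec(n_atoms = 400L + 100L * i, seed = seed + i)
    targets[[sprintf("target%d", i)]] <- make_structure(
      tspec, id = sprintf("target%d", i),
      path = file.path(out_dir, sprintf("target%d.pdb", i)))
  }

  tab <- make_training_set(table1_weights(), n = n_pairs, noise_sd = noise_sd,
                           seed = seed + 100L)
  write_training_table(tab, file.path(out_dir, "training_table.tsv"))

  netspec <- network_spec(seed = seed + 200L)
  net <- make_network(netspec)
  utils::write.table(net$network$edges, file.path(out_dir, "network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(node = names(net$priors), score = unname(net$priors)),
                     file.path(out_dir, "network_priors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = seed,
    structures = c(list(query = query$truth),
                   lapply(targets, function(t) t$truth)),
    training = list(true_weights = as.list(attr(tab, "true_weights")),
                    n = n_pairs, noise_sd = noise_sd),
    network = list(planted_top_path = net$top_path,
                   priors = as.list(net$priors))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
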