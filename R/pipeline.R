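#' Simulate a complete synthetic dataset on disk
#'
#' Runs every synthetic generator with substreams of the config's master
#' seed and writes the resulting dataset as plain-text files: network edge
#' list, pulldown table, disease model, null gene sets, and the ground
#' truth (as JSON, for benchmarking).  The disease model is generated
#' first so that one drug's targets can be planted in the disease
#' neighborhood (see [generate_truth()]).
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if needed); NULL keeps everything
#'   in memory.
#' @param n_disease_genes,freq_range passed to [generate_disease_spec()].
#' @param n_null_sets,genes_per_set passed to
#'   [generate_null_disease_list()].
#' @return Invisibly, a list with the generated objects and (when `dir` is
#'   given) the file paths.
#' @export
simulate_dataset <- function(config, dir = NULL,
                             n_disease_genes = 11L,
                             freq_range = c(0.07, 0.84),
                             n_null_sets = 100L, genes_per_set = 12L) {
  stopifnot(inherits(config, "sim_config"))
  net <- generate_ppi(config)
  disease <- generate_disease_spec(net, n_disease_genes, freq_range,
                                   seed = stage_seed(config$seed, "disease"))
  truth <- generate_truth(net, config, disease = disease)
  records <- generate_pulldowns(net, truth, config)
  nulls <- generate_null_disease_list(net, n_null_sets, genes_per_set,
                                      seed = stage_seed(config$seed, "nulls"))
  objects <- list(network = net, disease = disease, truth = truth,
                  pulldowns = records, null_sets = nulls, config = config)
  if (is.null(dir)) return(invisible(objects))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    edge_list = file.path(dir, "network_edges.tsv"),
    pulldowns = file.path(dir, "pulldowns.tsv"),
    disease = file.path(dir, "disease_model.json"),
    null_sets = file.path(dir, "null_gene_sets.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_edge_list(net, paths$edge_list)
  write_pulldowns(records, paths$pulldowns)
  write_disease_model(disease, paths$disease)
  write_null_sets(nulls, paths$null_sets)
  write_truth_json(truth, paths$truth)
  invisible(c(objects, list(paths = paths)))
}

default_params <- function() {
  list(alpha = 0.3, tol = 1e-10, max_iter = 10000L,
       normalization = "column", top_n = 500L,
       ratio_threshold = 2.0, min_avg_sc = 10.0, min_avg_sc_absent = 1.0,
       min_absent_in = 2L, nonkinase_factor = 0.25,
       null_p_method = "empirical_add_one", alias = NULL)
}

#' Run the full deconvolution-diffusion-scoring analysis in memory
#'
#' Executes, in order: the specificity gate and cross-drug rescue; per-drug
#' abundance profiles merged across cell types; network reduction to the
#' largest connected component and diffusion-matrix construction; random
#' walk with restart for every drug profile, every disease model, and
#' every null gene set (null sets are diffused with equal seed weights and
#' all-ones coefficients); deletion-weighted correlation scores;
#' empirical p-values; and the per-disease-model drug ranking.
#'
#' @param records pulldown table (see [read_pulldowns()]).
#' @param network a `ppi_network`.
#' @param disease_models named list of disease model specs.
#' @param null_sets list of null gene sets (character vectors).
#' @param params named list overriding entries of the defaults: `alpha`,
#'   `tol`, `max_iter`, `normalization`, `top_n`, `ratio_threshold`,
#'   `min_avg_sc`, `min_avg_sc_absent`, `min_absent_in`,
#'   `nonkinase_factor`, `null_p_method`, `alias`.
#' @return A `drugnet_report`: list with `results` (drug x disease-model
#'   score/p-value table), `rankings`, `profiles`, `calls`, `gate_stats`,
#'   `params`.
#' @export
analyze_dataset <- function(records, network, disease_models, null_sets,
                            params = list()) {
  check_pulldown_records(records)
  stopifnot(inherits(network, "ppi_network"))
  if (is.null(names(disease_models)) && length(disease_models))
    names(disease_models) <- sprintf("model%02d", seq_along(disease_models))
  pp <- utils::modifyList(default_params(), params)

  # --- deconvolution ---
  calls <- specificity_filter(records, pp$ratio_threshold, pp$min_avg_sc,
                              pp$min_avg_sc_absent)
  presence <- unique(records[!records$competed,
                             c("drug", "cell_type", "protein")])
  drugs <- sort(unique(records$drug))
  if (length(drugs) - 1L >= pp$min_absent_in) {
    calls <- rescue_by_cross_drug_absence(calls, presence, pp$min_absent_in)
  }
  profiles <- lapply(drugs, function(d) {
    merge_profiles(build_profile(calls, records, d, pp$nonkinase_factor))
  })
  names(profiles) <- drugs

  # --- network + diffusion ---
  lcc <- largest_connected_component(network)
  P <- build_diffusion_matrix(lcc, pp$normalization)
  rwr <- function(x0) random_walk_with_restart(P, x0, pp$alpha, pp$tol,
                                               pp$max_iter)
  drug_models <- lapply(profiles, function(pr) {
    rwr(seed_from_targets(lcc, pr, alias = pp$alias))
  })
  null_limits <- lapply(null_sets, function(gs) {
    spec <- structure(list(genes = stats::setNames(rep(1, length(gs)), gs),
                           driver = NULL), class = "disease_spec")
    rwr(seed_from_disease(lcc, spec, alias = pp$alias))
  })
  ones <- disease_coefficients(lcc$nodes, NULL)

  # --- scoring ---
  rows <- list()
  for (mid in names(disease_models)) {
    dm <- disease_models[[mid]]
    d_limit <- rwr(seed_from_disease(lcc, dm, alias = pp$alias))
    cc <- disease_coefficients(lcc$nodes, dm)
    for (dg in drugs) {
      t_limit <- drug_models[[dg]]
      obs <- correlation_score(d_limit, t_limit, cc, pp$top_n)$score
      nulls <- vapply(null_limits, function(nl) {
        correlation_score(nl, t_limit, ones, pp$top_n)$score
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        drug = dg, disease_model = mid, score = obs,
        n_null = length(nulls),
        p_value = null_pvalue(obs, nulls, pp$null_p_method),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rankings <- lapply(names(disease_models), function(mid) {
    rank_drugs(results, mid)
  })
  names(rankings) <- names(disease_models)

  gate_stats <- as.data.frame(table(drug = calls$drug,
                                    verdict = calls$verdict))
  structure(list(results = results, rankings = rankings,
                 profiles = profiles, calls = calls,
                 gate_stats = gate_stats, params = pp,
                 drug_models = drug_models),
            class = "drugnet_report")
}

#' @export
print.drugnet_report <- function(x, ...) {
  cat("<drugnet_report>\n")
  for (mid in names(x$rankings)) {
    r <- x$rankings[[mid]]
    cat(sprintf("  %s: %s\n", mid,
                paste(sprintf("%s (p=%.3g)", r$drug, r$p_value),
                      collapse = " > ")))
  }
  invisible(x)
}

#' Run the pipeline from a configuration file or list
#'
#' File-based front end to [analyze_dataset()]: reads the pulldown table,
#' edge list, disease model(s) and null gene sets named in the config,
#' runs the analysis, and writes every intermediate table, a run manifest
#' (parameters and file paths, as JSON) and the final ranking table to the
#' output directory.  Reruns with identical inputs produce bit-identical
#' outputs — the analysis itself involves no randomness.
#'
#' @param config YAML file path or list with elements `pulldowns`,
#'   `edge_list`, `disease_models` (named list of JSON paths),
#'   `null_sets`, `output_dir`, and optionally `params` (see
#'   [analyze_dataset()]).
#' @return The `drugnet_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  for (key in c("pulldowns", "edge_list", "disease_models", "null_sets",
                "output_dir")) {
    if (is.null(config[[key]])) stopf("config lacks '%s'", key)
  }
  for (pth in c(config$pulldowns, config$edge_list,
                unlist(config$disease_models), config$null_sets)) {
    if (!file.exists(pth)) stopf("input file not found: %s", pth)
  }
  records <- read_pulldowns(config$pulldowns)
  network <- read_edge_list(config$edge_list)
  disease_models <- lapply(config$disease_models, read_disease_model)
  null_sets <- read_null_sets(config$null_sets)
  params <- if (is.null(config$params)) list() else config$params

  report <- analyze_dataset(records, network, disease_models, null_sets,
                            params)

  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$results, file.path(out, "correlation_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$calls, file.path(out, "specificity_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (dg in names(report$profiles)) {
    write_profile(report$profiles[[dg]],
                  file.path(out, sprintf("profile_%s.tsv", dg)))
  }
  for (mid in names(report$rankings)) {
    utils::write.table(report$rankings[[mid]],
                       file.path(out, sprintf("ranking_%s.tsv", mid)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(inputs = config[c("pulldowns", "edge_list",
                                     "disease_models", "null_sets")],
                   params = report$params,
                   package_version = as.character(
                     utils::packageVersion("drugnet")))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  writeLines(report_markdown(report), file.path(out, "report.md"))
  invisible(report)
}

#' Human-readable markdown summary of an analysis report
#'
#' @param report a `drugnet_report`.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "drugnet_report"))
  lines <- c("# Drug-disease network correlation report", "")
  for (mid in names(report$rankings)) {
    r <- report$rankings[[mid]]
    lines <- c(lines,
               sprintf("## Disease model: %s", mid), "",
               "| rank | drug | score | n null | p-value |",
               "|-----:|------|------:|-------:|--------:|",
               sprintf("| %d | %s | %.4g | %d | %.3g |",
                       r$rank, r$drug, r$score, r$n_null, r$p_value),
               "")
  }
  gs <- report$gate_stats
  gs <- gs[gs$Freq > 0, ]
  lines <- c(lines, "## Specificity gate", "",
             "| drug | verdict | proteins |",
             "|------|---------|---------:|",
             sprintf("| %s | %s | %d |", gs$drug, gs$verdict, gs$Freq))
  lines
}
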