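#' Simulation configuration for synthetic chemical-proteomics data
#'
#' Bundles and validates every knob of the synthetic-data generators.  The
#' defaults mirror the experimental design the pipeline is built for: four
#' kinase inhibitors profiled in two cell lines, quadruplicate uncompeted
#' pulldowns per drug per cell line, and a single competition run per drug
#' per cell line performed with excess free drug.
#'
#' Spectral counts are drawn from a negative binomial with mean
#' `mu` and dispersion `dispersion` (variance `mu + dispersion * mu^2`);
#' `dispersion = 0` recovers the Poisson.  Planted direct targets have
#' per-replicate mean `affinity * cell_type_factor`; indirect binders (PPI
#' neighbors of planted targets) have that mean attenuated by
#' `indirect_attenuation`; background binders are consistently present at a
#' low mean unaffected by competition.  In competed runs the planted and
#' indirect means are multiplied by `competition_suppression`.
#' Sequence coverage follows the saturating curve
#' `100 * SC / (SC + coverage_halfsat)`, monotone in SC and bounded in
#' (0, 100].
#'
#' @param n_proteins number of proteins (network nodes).
#' @param attachment_parameter edges added per new node in the
#'   preferential-attachment graph generator.
#' @param graph_model `"preferential_attachment"` (scale-free, the default,
#'   since real interactomes are heavy-tailed) or `"erdos_renyi"`.
#' @param er_edge_prob edge probability for the Erdos-Renyi option.
#' @param n_drugs,n_cell_types numbers of drugs and cell types.
#' @param n_replicates_per_cell_type uncompeted replicates per drug per
#'   cell type (competition is always singlicate).
#' @param n_targets_per_drug planted direct targets per drug.
#' @param n_indirect_per_target PPI neighbors recruited per planted target.
#' @param affinity_range range of planted-target affinities; a target's
#'   affinity is its expected spectral count at cell-type factor 1.
#' @param cell_type_factors multiplicative expression factor per cell type
#'   (length `n_cell_types`).
#' @param indirect_attenuation factor applied to the recruiting target's
#'   affinity for indirect binders, in (0, 1].
#' @param competition_suppression factor applied to specific-binder means
#'   in competed runs, in (0, 1].
#' @param background_rate fraction of the proteome acting as background
#'   binders.
#' @param background_mean expected spectral count of a background binder.
#' @param background_kinase_fraction fraction of background binders flagged
#'   as kinases.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param coverage_halfsat spectral count at which sequence coverage
#'   reaches 50%.
#' @param seed master seed; all generator substreams derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1000L,
                       attachment_parameter = 3L,
                       graph_model = c("preferential_attachment",
                                       "erdos_renyi"),
                       er_edge_prob = 0.006,
                       n_drugs = 4L,
                       n_cell_types = 2L,
                       n_replicates_per_cell_type = 4L,
                       n_targets_per_drug = 8L,
                       n_indirect_per_target = 2L,
                       affinity_range = c(20, 60),
                       cell_type_factors = c(1, 0.8),
                       indirect_attenuation = 0.3,
                       competition_suppression = 0.1,
                       background_rate = 0.05,
                       background_mean = 2,
                       background_kinase_fraction = 0.1,
                       dispersion = 0.25,
                       coverage_halfsat = 20,
                       seed = 1L) {
  graph_model <- match.arg(graph_model)
  if (!is_count(n_proteins) || !is_count(attachment_parameter) ||
      n_proteins < attachment_parameter + 1L)
    stopf("need n_proteins >= attachment_parameter + 1")
  if (!(competition_suppression > 0 && competition_suppression <= 1))
    stopf("competition_suppression must be in (0, 1]")
  if (!(indirect_attenuation > 0 && indirect_attenuation <= 1))
    stopf("indirect_attenuation must be in (0, 1]")
  if (background_rate < 0 || background_rate > 1)
    stopf("background_rate must be in [0, 1]")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  if (length(cell_type_factors) != n_cell_types)
    stopf("cell_type_factors must have length n_cell_types")
  if (diff(range(affinity_range)) < 0 || min(affinity_range) <= 0)
    stopf("affinity_range must be positive and non-decreasing")
  structure(list(
    n_proteins = as.integer(n_proteins),
    attachment_parameter = as.integer(attachment_parameter),
    graph_model = graph_model,
    er_edge_prob = er_edge_prob,
    n_drugs = as.integer(n_drugs),
    n_cell_types = as.integer(n_cell_types),
    n_replicates_per_cell_type = as.integer(n_replicates_per_cell_type),
    n_targets_per_drug = as.integer(n_targets_per_drug),
    n_indirect_per_target = as.integer(n_indirect_per_target),
    affinity_range = affinity_range,
    cell_type_factors = cell_type_factors,
    indirect_attenuation = indirect_attenuation,
    competition_suppression = competition_suppression,
    background_rate = background_rate,
    background_mean = background_mean,
    background_kinase_fraction = background_kinase_fraction,
    dispersion = dispersion,
    coverage_halfsat = coverage_halfsat,
    seed = as.integer(seed)
  ), class = "sim_config")
}

sim_drug_names <- function(config) sprintf("drug%02d", seq_len(config$n_drugs))
sim_cell_names <- function(config) sprintf("cell%d", seq_len(config$n_cell_types))

#' Generate a synthetic protein-protein interaction network
#'
#' Grows a connected scale-free graph by preferential attachment: starting
#' from `attachment_parameter` seed nodes, each new node attaches to
#' `attachment_parameter` distinct existing nodes chosen with probability
#' proportional to degree + 1.  This yields exactly
#' `attachment_parameter * (n_proteins - attachment_parameter)` edges and a
#' heavy-tailed degree distribution, the salient feature of curated
#' interactomes.  An Erdos-Renyi variant (components reconnected minimally)
#' is available through the config.
#'
#' @param config a `sim_config`.
#' @return A connected `ppi_network` with `n_proteins` nodes, deterministic
#'   under the config seed.
#' @export
generate_ppi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_proteins
  nodes <- sprintf("P%05d", seq_len(n))
  with_seed(stage_seed(config$seed, "ppi"), {
    if (config$graph_model == "preferential_attachment") {
      m <- config$attachment_parameter
      n_edges <- m * (n - m)
      from <- character(n_edges)
      to <- character(n_edges)
      deg <- integer(n)
      k <- 0L
      for (v in seq.int(m + 1L, n)) {
        prev <- seq_len(v - 1L)
        tgt <- if (v - 1L <= m) prev else {
          sample(prev, m, replace = FALSE, prob = deg[prev] + 1)
        }
        idx <- k + seq_along(tgt)
        from[idx] <- nodes[v]
        to[idx] <- nodes[tgt]
        deg[v] <- deg[v] + length(tgt)
        deg[tgt] <- deg[tgt] + 1L
        k <- k + length(tgt)
      }
      ppi_network(cbind(from, to))
    } else {
      g <- igraph::sample_gnp(n, config$er_edge_prob, directed = FALSE)
      igraph::V(g)$name <- nodes
      comp <- igraph::components(g)
      if (comp$no > 1L) {
        # stitch smaller components onto the largest one
        main <- which.max(comp$csize)
        anchor <- nodes[comp$membership == main][1L]
        extra <- vapply(setdiff(seq_len(comp$no), main), function(k) {
          nodes[comp$membership == k][1L]
        }, character(1))
        g <- igraph::add_edges(g, rbind(rep(anchor, length(extra)), extra))
      }
      ppi_network(igraph::as_edgelist(g, names = TRUE))
    }
  })
}

#' Generate ground truth: planted targets, indirect binders, background
#'
#' Assigns each drug a set of planted direct targets (kinases) with
#' positive affinity weights, recruits PPI neighbors of those targets as
#' indirect binders, and designates a global set of background binders.
#' When a disease model is supplied, one drug (the "effective" drug, listed
#' in `effective_drug`) has its targets placed within graph distance 1-2 of
#' the disease genes, emulating a compound whose cellular targets sit in
#' the disease neighborhood; all other drugs' targets are placed uniformly.
#'
#' @param network a `ppi_network`.
#' @param config a `sim_config`.
#' @param disease optional disease model spec (see
#'   [generate_disease_spec()]); enables effective-drug placement.
#' @return An object of class `sim_truth` with elements `planted_targets`
#'   (per drug, named affinity vectors), `indirect_binders` (per drug,
#'   accession sets), `background_binders`, `kinase_flags`, and
#'   `effective_drug`.
#' @export
generate_truth <- function(network, config, disease = NULL) {
  stopifnot(inherits(network, "ppi_network"), inherits(config, "sim_config"))
  nodes <- network$nodes
  drugs <- sim_drug_names(config)
  nt <- config$n_targets_per_drug
  with_seed(stage_seed(config$seed, "truth"), {
    planted <- vector("list", length(drugs))
    names(planted) <- drugs
    effective <- NA_character_
    taken <- character(0)
    ring1 <- ring2 <- character(0)
    if (!is.null(disease)) {
      effective <- drugs[1L]
      seeds_on_net <- intersect(c(names(disease$genes), disease$driver), nodes)
      ring1 <- setdiff(unique(names(unlist(igraph::ego(
        network$graph, order = 1L, nodes = seeds_on_net, mindist = 1L)))),
        seeds_on_net)
      ring2 <- setdiff(unique(names(unlist(igraph::ego(
        network$graph, order = 2L, nodes = seeds_on_net, mindist = 1L)))),
        c(seeds_on_net, ring1))
    }
    for (d in drugs) {
      if (!is.null(disease) && d == effective) {
        # targets of the effective drug are interactors of the disease
        # proteins: drawn from the distance-1 ring, topped up from
        # distance 2 only when the direct neighborhood is too small
        p1 <- setdiff(ring1, taken)
        prot <- if (length(p1) >= nt) sample(p1, nt) else {
          p2 <- setdiff(ring2, taken)
          if (length(p1) + length(p2) < nt)
            stopf("disease neighborhood too small to plant %d targets", nt)
          c(p1, sample(p2, nt - length(p1)))
        }
      } else {
        pool <- setdiff(nodes, c(taken,
                                 if (!is.null(disease))
                                   c(names(disease$genes), disease$driver)))
        if (length(pool) < nt)
          stopf("not enough candidate nodes to plant %d targets for %s",
                nt, d)
        prot <- sample(pool, nt)
      }
      planted[[d]] <- stats::setNames(
        runif(nt, config$affinity_range[1L], config$affinity_range[2L]), prot)
      taken <- c(taken, prot)
    }
    indirect <- lapply(drugs, function(d) {
      own <- names(planted[[d]])
      picked <- character(0)
      for (p in own) {
        nb <- setdiff(names(igraph::neighbors(network$graph, p)), own)
        if (length(nb))
          picked <- c(picked,
                      sample(nb, min(config$n_indirect_per_target,
                                     length(nb))))
      }
      unique(picked)
    })
    names(indirect) <- drugs
    all_planted <- unique(unlist(lapply(planted, names)))
    bg_pool <- setdiff(nodes, all_planted)
    n_bg <- round(config$background_rate * length(nodes))
    background <- sort(sample(bg_pool, min(n_bg, length(bg_pool))))
    kin <- stats::setNames(
      runif(length(background)) < config$background_kinase_fraction,
      background)
    kin[all_planted] <- TRUE
    all_indirect <- setdiff(unique(unlist(indirect)), all_planted)
    kin[all_indirect] <- FALSE
    structure(list(planted_targets = planted,
                   indirect_binders = indirect,
                   background_binders = background,
                   kinase_flags = kin,
                   effective_drug = effective),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d drugs, %d-%d planted targets each, %d background binders\n",
    length(x$planted_targets),
    min(lengths(x$planted_targets)), max(lengths(x$planted_targets)),
    length(x$background_binders)))
  if (!is.na(x$effective_drug))
    cat("  effective drug:", x$effective_drug, "\n")
  invisible(x)
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu,
                                                 size = 1 / dispersion)
}

#' Generate replicate competition-pulldown tables
#'
#' Simulates, for every drug and cell type, the uncompeted replicate
#' pulldowns and one competed (excess free drug) run.  Planted targets and
#' indirect binders have their expected counts multiplied by
#' `competition_suppression` in the competed run; background binders are
#' unaffected by competition and, modeling the sticky proteins that every
#' pulldown recovers, are drawn with a minimum count of 1 when
#' `background_mean > 1`.  Sequence coverage is the saturating function of
#' spectral count described in [sim_config()].  Only detected proteins
#' (spectral count > 0) are reported, as in real protein-level tables.
#'
#' @param network a `ppi_network`.
#' @param truth a `sim_truth`.
#' @param config a `sim_config`.
#' @return A data frame with columns `drug`, `cell_type`, `replicate`,
#'   `competed`, `protein`, `is_kinase`, `spectral_count`,
#'   `seq_coverage_pct`.
#' @export
generate_pulldowns <- function(network, truth, config) {
  stopifnot(inherits(network, "ppi_network"), inherits(config, "sim_config"))
  if (!inherits(truth, "sim_truth") || !length(truth$planted_targets))
    stopf("empty or invalid truth object")
  all_prot <- unique(c(unlist(lapply(truth$planted_targets, names)),
                       unlist(truth$indirect_binders),
                       truth$background_binders))
  if (!all(all_prot %in% network$nodes))
    stopf("truth refers to proteins outside the network")
  drugs <- names(truth$planted_targets)
  cells <- sim_cell_names(config)
  sup <- config$competition_suppression
  with_seed(stage_seed(config$seed, "pulldowns"), {
    out <- list()
    for (d in drugs) {
      aff <- truth$planted_targets[[d]]
      ind <- truth$indirect_binders[[d]]
      # indirect binder mean: attenuated affinity of its strongest
      # recruiting planted target
      ind_aff <- vapply(ind, function(p) {
        nb <- names(igraph::neighbors(network$graph, p))
        config$indirect_attenuation * max(aff[intersect(nb, names(aff))])
      }, numeric(1))
      bg <- setdiff(truth$background_binders, c(names(aff), ind))
      prot <- c(names(aff), ind, bg)
      base_mu <- c(unname(aff), unname(ind_aff),
                   rep(config$background_mean, length(bg)))
      specific <- c(rep(TRUE, length(aff) + length(ind)),
                    rep(FALSE, length(bg)))
      is_bg <- !specific
      kin <- unname(truth$kinase_flags[prot])
      kin[is.na(kin)] <- FALSE
      for (ci in seq_along(cells)) {
        f <- config$cell_type_factors[ci]
        reps <- c(sprintf("R%d", seq_len(config$n_replicates_per_cell_type)),
                  "C1")
        for (r in reps) {
          competed <- r == "C1"
          mu <- base_mu * f
          mu[specific] <- mu[specific] * if (competed) sup else 1
          sc <- integer(length(prot))
          sc[!is_bg] <- nb_draw(sum(!is_bg), mu[!is_bg], config$dispersion)
          if (any(is_bg)) {
            mub <- mu[is_bg]
            if (config$background_mean > 1) {
              sc[is_bg] <- 1L + nb_draw(sum(is_bg), pmax(mub - 1, 1e-8),
                                        config$dispersion)
            } else {
              sc[is_bg] <- nb_draw(sum(is_bg), mub, config$dispersion)
            }
          }
          keep <- sc > 0L
          if (!any(keep)) next
          out[[length(out) + 1L]] <- data.frame(
            drug = d, cell_type = cells[ci], replicate = r,
            competed = competed, protein = prot[keep],
            is_kinase = kin[keep], spectral_count = sc[keep],
            seq_coverage_pct =
              100 * sc[keep] / (sc[keep] + config$coverage_halfsat),
            stringsAsFactors = FALSE)
        }
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate a disease model specification
#'
#' Samples `n_genes` distinct network nodes as disease genes with deletion
#' frequencies uniform in `freq_range`, and designates one additional node
#' as the disease driver (the fusion-kinase analog), carried at frequency
#' 1.0.  The driver is kept separate from the deletion list: it seeds the
#' disease diffusion at full weight but receives no deletion coefficient.
#'
#' @param network a `ppi_network`.
#' @param n_genes number of deleted disease genes (0 gives a driver-only
#'   model).
#' @param freq_range deletion-frequency range, within (0, 1].
#' @param seed integer seed.
#' @return A list of class `disease_spec` with elements `genes` (named
#'   frequency vector) and `driver`.
#' @export
generate_disease_spec <- function(network, n_genes = 11L,
                                  freq_range = c(0.07, 0.84), seed = 1L) {
  stopifnot(inherits(network, "ppi_network"))
  if (length(freq_range) != 2L || diff(freq_range) < 0)
    stopf("freq_range must be a non-empty (lo, hi) range")
  if (n_genes + 1L > length(network$nodes))
    stopf("n_genes exceeds the number of network nodes")
  with_seed(seed, {
    picked <- sample(network$nodes, n_genes + 1L)
    driver <- picked[1L]
    genes <- if (n_genes > 0L) {
      stats::setNames(runif(n_genes, freq_range[1L], freq_range[2L]),
                      picked[-1L])
    } else {
      stats::setNames(numeric(0), character(0))
    }
    structure(list(genes = genes, driver = driver), class = "disease_spec")
  })
}

#' Generate null disease gene sets
#'
#' Samples `n_sets` gene sets (without replacement within each set; sets
#' may overlap each other) from the network nodes.  These stand in for a
#' catalog of diseases unrelated to the one under study and are used to
#' build the empirical null distribution of correlation scores.
#'
#' @param network a `ppi_network`.
#' @param n_sets number of null sets (>= 1).
#' @param genes_per_set genes per set (<= number of nodes).
#' @param seed integer seed.
#' @return A list of character vectors of accessions.
#' @export
generate_null_disease_list <- function(network, n_sets = 100L,
                                       genes_per_set = 12L, seed = 1L) {
  stopifnot(inherits(network, "ppi_network"))
  if (!is_count(n_sets) || n_sets < 1L) stopf("n_sets must be >= 1")
  if (genes_per_set > length(network$nodes))
    stopf("genes_per_set exceeds the number of network nodes")
  with_seed(seed, {
    lapply(seq_len(n_sets), function(i) sample(network$nodes, genes_per_set))
  })
}
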