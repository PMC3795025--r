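# Fixture builders shared across test files.  Everything is constructed in
# code; no data files.

# One pulldown row
pd_row <- function(drug, cell_type, replicate, competed, protein,
                   is_kinase, sc, cov = 100 * sc / (sc + 20)) {
  data.frame(drug = drug, cell_type = cell_type, replicate = replicate,
             competed = competed, protein = protein, is_kinase = is_kinase,
             spectral_count = sc, seq_coverage_pct = cov,
             stringsAsFactors = FALSE)
}

# Uncompeted quadruplicate + competed singlicate for one protein with
# given per-replicate counts
pd_block <- function(drug, ct, protein, kinase, unc_counts, comp_count) {
  rows <- lapply(seq_along(unc_counts), function(i) {
    pd_row(drug, ct, paste0("R", i), FALSE, protein, kinase, unc_counts[i])
  })
  if (!is.na(comp_count))
    rows <- c(rows, list(pd_row(drug, ct, "C1", TRUE, protein, kinase,
                                comp_count)))
  out <- do.call(rbind, rows)
  out[out$spectral_count > 0, ]
}

# A small connected random graph as a ppi_network (Erdos-Renyi + stitch)
random_connected_net <- function(n, seed, p = max(0.05, 2 * log(n) / n)) {
  cfg <- sim_config(n_proteins = n, attachment_parameter = 1L,
                    graph_model = "erdos_renyi", er_edge_prob = p,
                    seed = seed)
  generate_ppi(cfg)
}

# Path graph on labelled nodes
path_net <- function(n) {
  lab <- sprintf("N%02d", seq_len(n))
  ppi_network(cbind(lab[-n], lab[-1]))
}

# Independent reference for the RWR limit: direct linear solve
rwr_direct_solve <- function(P, x0, alpha = 0.3) {
  n <- length(x0)
  M <- diag(n) - (1 - alpha) * as.matrix(P$P)
  as.numeric(solve(M, alpha * as.numeric(x0)))
}

# Brute-force one-sided KS statistic: scan every pooled sample point
ks_D_bruteforce <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) mean(b <= x) - mean(a <= x), numeric(1)))
}
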