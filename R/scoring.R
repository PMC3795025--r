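#' Deletion coefficients of a disease model
#'
#' Per-node coefficients `c_i` weighting the correlation score: 1 for
#' every node outside the disease deletion list, `1 - frequency` for a
#' deleted gene.  The disease driver is not a deletion and keeps
#' coefficient 1.  A frequently deleted gene thus contributes little to
#' the score — its protein is often simply not there to be drugged.
#'
#' @param nodes node order (e.g. `network_nodes(net)`).
#' @param model a `disease_spec`, or NULL / driver-only for all-ones.
#' @return Named numeric vector of coefficients in \[0, 1\].
#' @export
disease_coefficients <- function(nodes, model = NULL) {
  cc <- stats::setNames(rep(1, length(nodes)), nodes)
  if (!is.null(model) && length(model$genes)) {
    g <- intersect(names(model$genes), nodes)
    cc[g] <- 1 - model$genes[g]
  }
  cc
}

#' Drug-disease network correlation score
#'
#' Sums the deletion-weighted products `c_i * d_i * t_i` of the disease
#' (`d`) and drug-treatment (`t`) diffusion limits over the set S of the
#' `top_n` largest products.  The score measures how much of the drug's
#' network influence lands on the disease-influenced, still-present part
#' of the proteome.  Ties in the product ranking are broken by node order.
#'
#' @param d disease network model (probability vector).
#' @param t drug treatment network model (probability vector).
#' @param coefficients per-node deletion coefficients `c_i` (default 1).
#' @param top_n size of the summation set S.
#' @param rank_by `"weighted"` ranks nodes by the full summand
#'   `c_i d_i t_i` (default); `"product"` ranks by `d_i t_i`.
#' @return List with `score` and `selected` (the node names of S).
#' @export
correlation_score <- function(d, t, coefficients = NULL, top_n = 500L,
                              rank_by = c("weighted", "product")) {
  rank_by <- match.arg(rank_by)
  if (length(d) != length(t) || !identical(names(d), names(t)))
    stopf("d and t must share the same node index")
  if (is.null(coefficients)) {
    coefficients <- stats::setNames(rep(1, length(d)), names(d))
  }
  if (!identical(names(coefficients), names(d)))
    stopf("coefficients must share the node index of d and t")
  if (!is_count(top_n) || top_n < 1L || top_n > length(d))
    stopf("top_n must lie in [1, %d]", length(d))
  prod_full <- as.numeric(coefficients) * as.numeric(d) * as.numeric(t)
  key <- if (rank_by == "weighted") prod_full else as.numeric(d) * as.numeric(t)
  sel <- order(-key, seq_along(key))[seq_len(top_n)]
  list(score = sum(prod_full[sel]), selected = names(d)[sel])
}

#' Empirical p-value against a null score distribution
#'
#' Normalizes a raw correlation score against scores of the same drug on
#' unrelated (null) disease models.  The default add-one empirical
#' p-value `(1 + #\{null >= observed\}) / (1 + N)` is conservative and never
#' 0; a Gaussian upper tail fitted to the null sample is available for
#' short null lists.
#'
#' @param observed raw correlation score.
#' @param null_scores numeric vector of null scores.
#' @param method `"empirical_add_one"` (default) or `"gaussian_fit"`.
#' @return p-value in (0, 1].
#' @export
null_pvalue <- function(observed, null_scores,
                        method = c("empirical_add_one", "gaussian_fit")) {
  method <- match.arg(method)
  if (!length(null_scores)) stopf("null score list is empty")
  if (length(null_scores) < 10L)
    warning("fewer than 10 null scores; p-value is coarse", call. = FALSE)
  if (method == "empirical_add_one") {
    (1 + sum(null_scores >= observed)) / (1 + length(null_scores))
  } else {
    min(1, stats::pnorm(observed, mean = mean(null_scores),
                        sd = stats::sd(null_scores), lower.tail = FALSE))
  }
}

#' Rank drugs by normalized correlation with a disease model
#'
#' Orders drugs by ascending p-value (descending predicted impact on the
#' disease network); ties broken by descending raw score, then drug name.
#'
#' @param results data frame with columns `drug`, `disease_model`,
#'   `score`, `p_value` (one row per drug for the chosen model).
#' @param disease_model_id which disease model to rank on.
#' @return The subset of `results` for that model, ordered, with a `rank`
#'   column.
#' @export
rank_drugs <- function(results, disease_model_id) {
  r <- results[results$disease_model == disease_model_id, , drop = FALSE]
  if (nrow(r) == 0L) stopf("no results for disease model '%s'",
                           disease_model_id)
  if (anyDuplicated(r$drug)) stopf("duplicate drugs for one disease model")
  r <- r[order(r$p_value, -r$score, r$drug), , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  rownames(r) <- NULL
  r
}

#' Hypergeometric enrichment of non-kinase binders among kinase interactors
#'
#' Direct (kinase) drug binders should recruit their interaction partners
#' into the eluate, so genuine indirect (non-kinase) binders ought to sit
#' among the network neighbors of the kinase set more often than chance.
#' With N network nodes, K distinct neighbors of the kinase set (kinases
#' themselves excluded), and n non-kinases of which k are neighbors, the
#' upper hypergeometric tail P(X >= k) quantifies the enrichment.
#'
#' @param net a `ppi_network`.
#' @param kinases accessions of the (direct-binder) kinase set.
#' @param nonkinases accessions of the non-kinase binders; disjoint from
#'   `kinases`.
#' @return List with `N`, `K`, `n`, `k`, `p`.
#' @export
interactor_enrichment <- function(net, kinases, nonkinases) {
  stopifnot(inherits(net, "ppi_network"))
  if (!length(kinases) || !length(nonkinases))
    stopf("kinase and non-kinase sets must be non-empty")
  if (length(intersect(kinases, nonkinases)))
    stopf("kinase and non-kinase sets must be disjoint")
  if (!all(c(kinases, nonkinases) %in% net$nodes))
    stopf("all proteins must be network nodes")
  nb <- unique(names(unlist(
    igraph::ego(net$graph, order = 1L, nodes = kinases, mindist = 1L))))
  nb <- setdiff(nb, kinases)
  N <- length(net$nodes)
  K <- length(nb)
  n <- length(nonkinases)
  k <- length(intersect(nonkinases, nb))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(N = N, K = K, n = n, k = k, p = p)
}
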