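#' Seed vector from a drug target profile
#'
#' Maps the proteins of a target profile onto the network and assigns
#' initial probabilities proportional to their abundance scores A; all
#' other nodes start at 0.  Targets that cannot be mapped are dropped with
#' a message and the remaining weights renormalized.  An alias table
#' translates non-network identifiers (e.g. a fusion protein recorded under
#' its own name) to network accessions before mapping; when an alias and
#' its canonical accession both carry scores, the maximum is kept,
#' consistent with the profile-merge rule.
#'
#' @param net a `ppi_network`.
#' @param profile a `target_profile` (or a named numeric vector of scores).
#' @param alias optional named character vector, `alias -> accession`.
#' @return A probability vector: named numeric over `network_nodes(net)`,
#'   summing to 1.
#' @export
seed_from_targets <- function(net, profile, alias = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  scores <- if (inherits(profile, "target_profile")) profile$scores else profile
  if (!length(scores)) stopf("profile carries no scores")
  scores <- apply_alias(scores, alias)
  seed_vector(net, scores, what = "target")
}

#' Seed vector from a disease model
#'
#' Average-patient model: initial probabilities proportional to gene
#' deletion frequencies, with the disease driver added at frequency 1.0.
#' Copy-number (cell-line) model: genes with copy number below
#' `deleted_below` enter with equal weight, plus the driver at weight 1.0
#' before normalization; amplified genes receive no seed weight.
#'
#' @param net a `ppi_network`.
#' @param model a `disease_spec` (elements `genes`, `driver`) or a
#'   copy-number model: list with `copy_numbers` (named numeric), `driver`,
#'   and optional `deleted_below` (default -0.5).
#' @param alias optional named character vector, `alias -> accession`.
#' @return A probability vector over `network_nodes(net)`.
#' @export
seed_from_disease <- function(net, model, alias = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (!is.null(model$copy_numbers)) {
    thr <- if (is.null(model$deleted_below)) -0.5 else model$deleted_below
    del <- names(model$copy_numbers)[model$copy_numbers < thr]
    w <- stats::setNames(rep(1, length(del)), del)
  } else {
    w <- model$genes
  }
  if (!is.null(model$driver)) {
    dw <- stats::setNames(1, model$driver)
    w <- c(w[setdiff(names(w), model$driver)], dw)
  }
  if (!length(w)) stopf("disease model has no seed genes")
  w <- apply_alias(w, alias)
  seed_vector(net, w, what = "disease gene")
}

apply_alias <- function(w, alias) {
  if (is.null(alias)) return(w)
  hit <- names(w) %in% names(alias)
  names(w)[hit] <- unname(alias[names(w)[hit]])
  if (anyDuplicated(names(w))) {
    w <- vapply(split(unname(w), names(w)), max, numeric(1))
  }
  w
}

seed_vector <- function(net, w, what) {
  if (any(w < 0)) stopf("seed weights must be non-negative")
  mapped <- names(w) %in% net$nodes
  if (!any(mapped))
    stopf("no %s maps onto the network", what)
  if (any(!mapped))
    message(sum(!mapped), " ", what, "(s) not in the network; dropped: ",
            paste(names(w)[!mapped], collapse = ", "))
  w <- w[mapped]
  if (sum(w) <= 0) stopf("all mapped %s weights are zero", what)
  x0 <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  x0[names(w)] <- x0[names(w)] + w  # duplicates already collapsed upstream
  x0 / sum(x0)
}

#' Random walk with restart
#'
#' Iterates `x_{i+1} = (1 - alpha) P x_i + alpha x_0` until the L1 change
#' between successive iterates falls below `tol`.  With a column-stochastic
#' `P` every iterate is a probability distribution and the limit solves
#' `x = alpha (I - (1 - alpha) P)^{-1} x_0`; the iteration contracts with
#' ratio at most `1 - alpha`, so convergence is geometric.  The limit is
#' the network model of the seeded signal: nodes close (in the
#' random-walk sense) to heavily seeded nodes receive high probability.
#'
#' @param P a `diffusion_matrix` (or a square matrix sharing `x0`'s index).
#' @param x0 seed probability vector (named, non-negative, sums to 1).
#' @param alpha restart weight in (0, 1]; 0.3 by default — the walker
#'   returns to the seeds with probability alpha at each step, so larger
#'   alpha keeps the limit more local to the seeds.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   final residual.
#' @return The limit probability vector, with attribute `iterations`.
#' @export
random_walk_with_restart <- function(P, x0, alpha = 0.3, tol = 1e-10,
                                     max_iter = 10000L) {
  if (inherits(P, "diffusion_matrix")) {
    if (!identical(names(x0), P$nodes))
      stopf("x0 and P do not share the same node index")
    P <- P$P
  }
  if (!(alpha > 0 && alpha <= 1)) stopf("alpha must lie in (0, 1]")
  if (abs(sum(x0) - 1) > 1e-9) stopf("x0 must sum to 1")
  nms <- names(x0)
  x <- as.numeric(x0)
  x0n <- x
  if (alpha == 1) {
    res <- stats::setNames(x0n, nms)
    attr(res, "iterations") <- 0L
    return(res)
  }
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric((1 - alpha) * (P %*% x)) + alpha * x0n
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tol) {
      res <- stats::setNames(x, nms)
      attr(res, "iterations") <- it
      return(res)
    }
  }
  stopf("random walk did not converge in %d iterations (L1 residual %.3e)",
        max_iter, delta)
}
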