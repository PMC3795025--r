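#' Specificity gate on competition pulldowns
#'
#' Classifies every (drug, cell type, protein) as a specific or nonspecific
#' binder by comparing average spectral counts between uncompeted and
#' competed (excess free drug) runs.  A protein still detected in the
#' competed run is specific when the uncompeted/competed ratio reaches
#' `ratio_threshold` and the average uncompeted count reaches `min_avg_sc`
#' (`specific_by_ratio`).  A protein absent from the competed run is
#' specific already at the lowered count threshold `min_avg_sc_absent`
#' (`specific_by_absence`).  Averages are taken over all replicates of the
#' drug and cell type, counting a replicate in which the protein was not
#' detected as 0.
#'
#' @param records pulldown data frame with columns `drug`, `cell_type`,
#'   `replicate`, `competed`, `protein`, `is_kinase`, `spectral_count`,
#'   `seq_coverage_pct`.
#' @param ratio_threshold minimum uncompeted/competed spectral-count ratio.
#' @param min_avg_sc minimum average uncompeted spectral count for the
#'   ratio rule.
#' @param min_avg_sc_absent minimum average uncompeted spectral count when
#'   the protein is absent from the competed run.
#' @return A data frame of specificity calls: one row per
#'   (drug, cell_type, protein) with `avg_sc_uncompeted`,
#'   `avg_sc_competed`, `ratio` (NA when the competed average is 0) and
#'   `verdict` in `specific_by_ratio`, `specific_by_absence`, `rescued`,
#'   `nonspecific`.
#' @export
specificity_filter <- function(records, ratio_threshold = 2.0,
                               min_avg_sc = 10.0, min_avg_sc_absent = 1.0) {
  check_pulldown_records(records)
  out <- list()
  for (d in unique(records$drug)) {
    rd <- records[records$drug == d, ]
    if (!any(!rd$competed))
      stopf("no uncompeted pulldown data for drug '%s'", d)
    for (ct in unique(rd$cell_type)) {
      rc <- rd[rd$cell_type == ct, ]
      n_unc <- length(unique(rc$replicate[!rc$competed]))
      n_com <- length(unique(rc$replicate[rc$competed]))
      if (n_unc == 0L)
        stopf("no uncompeted replicates for drug '%s' in '%s'", d, ct)
      prots <- sort(unique(rc$protein))
      avg_u <- vapply(prots, function(p) {
        sum(rc$spectral_count[!rc$competed & rc$protein == p]) / n_unc
      }, numeric(1))
      avg_c <- if (n_com > 0L) {
        vapply(prots, function(p) {
          sum(rc$spectral_count[rc$competed & rc$protein == p]) / n_com
        }, numeric(1))
      } else {
        rep(0, length(prots))
      }
      ratio <- ifelse(avg_c > 0, avg_u / avg_c, NA_real_)
      verdict <- ifelse(
        avg_c == 0,
        ifelse(avg_u >= min_avg_sc_absent, "specific_by_absence",
               "nonspecific"),
        ifelse(!is.na(ratio) & ratio >= ratio_threshold &
                 avg_u >= min_avg_sc,
               "specific_by_ratio", "nonspecific"))
      out[[length(out) + 1L]] <- data.frame(
        protein = prots, drug = d, cell_type = ct,
        avg_sc_uncompeted = avg_u, avg_sc_competed = avg_c,
        ratio = ratio, verdict = verdict,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

check_pulldown_records <- function(records) {
  need <- c("drug", "cell_type", "replicate", "competed", "protein",
            "is_kinase", "spectral_count", "seq_coverage_pct")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("pulldown table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(records$spectral_count < 0))
    stopf("negative spectral counts in pulldown table")
  if (any(records$seq_coverage_pct < 0 | records$seq_coverage_pct > 100))
    stopf("sequence coverage outside [0, 100]")
  invisible(records)
}

#' Rescue proteins absent from other drugs' pulldowns
#'
#' A protein that fails the competition gate for one drug but is absent
#' from the uncompeted pulldowns of at least `min_absent_in` other drugs
#' (same cell type) is itself evidence of specificity — a promiscuous
#' background binder would appear everywhere.  Such proteins are upgraded
#' from `nonspecific` to `rescued`; all other verdicts are untouched.
#'
#' @param calls specificity-call table from [specificity_filter()].
#' @param presence data frame (`drug`, `cell_type`, `protein`) listing the
#'   proteins detected in each drug's uncompeted pulldowns; typically
#'   `unique(records[!records$competed, c("drug","cell_type","protein")])`.
#' @param min_absent_in minimum number of other drugs lacking the protein.
#' @return The calls table with upgraded verdicts.
#' @export
rescue_by_cross_drug_absence <- function(calls, presence, min_absent_in = 2L) {
  stopifnot(all(c("drug", "cell_type", "protein") %in% names(presence)))
  for (ct in unique(calls$cell_type)) {
    drugs_ct <- unique(presence$drug[presence$cell_type == ct])
    if (min_absent_in > length(drugs_ct) - 1L)
      stopf("min_absent_in = %d exceeds the %d other drug(s) in '%s'",
            min_absent_in, length(drugs_ct) - 1L, ct)
    idx <- which(calls$cell_type == ct & calls$verdict == "nonspecific")
    for (i in idx) {
      others <- setdiff(drugs_ct, calls$drug[i])
      seen_in <- unique(presence$drug[
        presence$cell_type == ct & presence$protein == calls$protein[i]])
      if (length(setdiff(others, seen_in)) >= min_absent_in)
        calls$verdict[i] <- "rescued"
    }
  }
  calls
}

#' Eluate abundance score
#'
#' The per-protein binding-strength proxy `A = SC * SeqCov` (spectral count
#' times percent sequence coverage), comparable to other semi-quantitative
#' spectral abundance indices.  Non-kinase scores are down-weighted by
#' `nonkinase_factor` to reflect their likely indirect (secondary binder)
#' nature.
#'
#' @param sc spectral count(s), >= 0.
#' @param seq_coverage_pct sequence coverage in percent, in \[0, 100\].
#' @param is_kinase logical flag(s).
#' @param nonkinase_factor weight applied to non-kinase scores.
#' @return Numeric score(s), units count x percent.
#' @export
abundance_score <- function(sc, seq_coverage_pct, is_kinase,
                            nonkinase_factor = 0.25) {
  if (any(sc < 0)) stopf("spectral counts must be >= 0")
  if (any(seq_coverage_pct < 0 | seq_coverage_pct > 100))
    stopf("sequence coverage must lie in [0, 100]")
  sc * seq_coverage_pct * ifelse(is_kinase, 1, nonkinase_factor)
}

#' Build per-cell-type target profiles for one drug
#'
#' Collects every protein whose specificity verdict is not `nonspecific`
#' and scores it with [abundance_score()] using replicate-averaged
#' uncompeted spectral count and coverage (a replicate without the protein
#' contributes 0 to both averages).
#'
#' @param calls specificity-call table (after any rescue step).
#' @param records the pulldown table the calls were derived from.
#' @param drug drug identifier.
#' @param nonkinase_factor passed to [abundance_score()].
#' @return A named list of `target_profile` objects, one per cell type.
#' @export
build_profile <- function(calls, records, drug, nonkinase_factor = 0.25) {
  if (!drug %in% calls$drug) stopf("unknown drug '%s'", drug)
  check_pulldown_records(records)
  cd <- calls[calls$drug == drug & calls$verdict != "nonspecific", ]
  rd <- records[records$drug == drug & !records$competed, ]
  cells <- unique(calls$cell_type[calls$drug == drug])
  profiles <- lapply(cells, function(ct) {
    cc <- cd[cd$cell_type == ct, ]
    rc <- rd[rd$cell_type == ct, ]
    n_rep <- length(unique(rc$replicate))
    if (nrow(cc) == 0L) {
      warning(sprintf("no specific proteins for %s in %s", drug, ct),
              call. = FALSE)
      return(new_target_profile(drug, numeric(0),
                                provenance = empty_provenance()))
    }
    rows <- lapply(seq_len(nrow(cc)), function(i) {
      p <- cc$protein[i]
      ri <- rc[rc$protein == p, ]
      avg_sc <- sum(ri$spectral_count) / n_rep
      avg_cov <- sum(ri$seq_coverage_pct) / n_rep
      kin <- if (nrow(ri)) ri$is_kinase[1L] else FALSE
      data.frame(protein = p, cell_type = ct,
                 A = abundance_score(avg_sc, avg_cov, kin, nonkinase_factor),
                 is_kinase = kin, verdict = cc$verdict[i],
                 stringsAsFactors = FALSE)
    })
    prov <- do.call(rbind, rows)
    new_target_profile(drug, stats::setNames(prov$A, prov$protein), prov)
  })
  stats::setNames(profiles, cells)
}

empty_provenance <- function() {
  data.frame(protein = character(0), cell_type = character(0),
             A = numeric(0), is_kinase = logical(0), verdict = character(0),
             stringsAsFactors = FALSE)
}

new_target_profile <- function(drug, scores, provenance) {
  structure(list(drug = drug, scores = scores, provenance = provenance),
            class = "target_profile")
}

#' @export
print.target_profile <- function(x, ...) {
  cat(sprintf("<target_profile> %s: %d specific protein(s)\n",
              x$drug, length(x$scores)))
  if (length(x$scores)) {
    top <- sort(x$scores, decreasing = TRUE)
    print(utils::head(round(top, 1), 5))
  }
  invisible(x)
}

#' Merge cell-type profiles of one drug by elementwise maximum
#'
#' Cell-line-dependent profiles are combined by taking, per protein, the
#' maximum abundance score across profiles — the optimal observed binding
#' potential.  The merged profile covers the union of proteins; the
#' operation is associative, commutative and idempotent.
#'
#' @param profiles list of `target_profile` objects for the same drug.
#' @return A single merged `target_profile` whose provenance records the
#'   cell type contributing each maximum.
#' @export
merge_profiles <- function(profiles) {
  if (inherits(profiles, "target_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "target_profile")))
  drugs <- unique(vapply(profiles, `[[`, character(1), "drug"))
  if (length(drugs) != 1L)
    stopf("cannot merge profiles of different drugs: %s",
          paste(drugs, collapse = ", "))
  prov <- do.call(rbind, lapply(profiles, `[[`, "provenance"))
  if (nrow(prov) == 0L)
    return(new_target_profile(drugs, numeric(0), empty_provenance()))
  keep <- unlist(lapply(split(seq_len(nrow(prov)), prov$protein),
                        function(ix) ix[which.max(prov$A[ix])]))
  prov <- prov[keep, , drop = FALSE]
  prov <- prov[order(prov$protein), , drop = FALSE]
  rownames(prov) <- NULL
  new_target_profile(drugs, stats::setNames(prov$A, prov$protein), prov)
}

#' One-sided two-sample Kolmogorov-Smirnov specificity test
#'
#' Tests whether per-replicate abundance scores in `values_a` are
#' stochastically larger than those in `values_b` (replicates in which the
#' protein was absent contribute 0).  The statistic is
#' `D = sup_x [ECDF_b(x) - ECDF_a(x)]`, evaluated at every point of the
#' pooled sample, and the default p-value is the one-sided asymptotic tail
#' `exp(-2 D^2 n m / (n + m))`, clipped to (0, 1]; `D <= 0` gives p = 1.
#' An exact conditional tail is available via `method = "exact"`.
#'
#' @param values_a replicate abundance scores for the contrast of interest.
#' @param values_b comparison replicate scores.
#' @param method `"asymptotic"` (default) or `"exact"`
#'   (via [stats::ks.test()]).
#' @return A list with elements `D`, `p`, `n`, `m`.
#' @export
ks_specificity_pvalue <- function(values_a, values_b,
                                  method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  if (!length(values_a) || !length(values_b))
    stopf("both samples must be non-empty")
  n <- length(values_a)
  m <- length(values_b)
  pooled <- sort(unique(c(values_a, values_b)))
  ecdf_a <- vapply(pooled, function(x) mean(values_a <= x), numeric(1))
  ecdf_b <- vapply(pooled, function(x) mean(values_b <= x), numeric(1))
  D <- max(ecdf_b - ecdf_a)
  if (D <= 0) return(list(D = max(D, 0), p = 1, n = n, m = m))
  p <- if (method == "asymptotic") {
    min(1, exp(-2 * D^2 * n * m / (n + m)))
  } else {
    # ks.test's "greater" alternative: ECDF of x lies above that of y,
    # i.e. b stochastically smaller than a
    suppressWarnings(
      stats::ks.test(values_b, values_a, alternative = "greater",
                     exact = TRUE)$p.value)
  }
  list(D = D, p = p, n = n, m = m)
}
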