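test_that("specificity gate applies the ratio, count and absence rules", {
  recs <- rbind(
    pd_block("dA", "c1", "P1", TRUE, c(20, 20, 20, 20), 5),   # ratio 4, avg 20
    pd_block("dA", "c1", "P2", TRUE, c(2, 2, 1, 1), NA),      # absent, avg 1.5
    pd_block("dA", "c1", "P3", TRUE, c(8, 8, 8, 8), 2),       # ratio 4, avg 8
    pd_block("dA", "c1", "P4", FALSE, c(12, 12, 12, 12), 10), # ratio 1.2
    pd_block("dA", "c1", "P5", TRUE, c(1, 0, 0, 0), NA)       # absent, avg .25
  )
  calls <- specificity_filter(recs)
  v <- setNames(calls$verdict, calls$protein)
  expect_identical(v[["P1"]], "specific_by_ratio")
  expect_identical(v[["P2"]], "specific_by_absence")
  expect_identical(v[["P3"]], "nonspecific")
  expect_identical(v[["P4"]], "nonspecific")
  expect_identical(v[["P5"]], "nonspecific")
  expect_equal(calls$avg_sc_uncompeted[calls$protein == "P2"], 1.5)
  expect_equal(calls$ratio[calls$protein == "P1"], 4)
  expect_true(is.na(calls$ratio[calls$protein == "P2"]))
})

test_that("averages treat a replicate without the protein as zero", {
  recs <- rbind(
    pd_block("dA", "c1", "P1", TRUE, c(8, 0, 0, 0), NA),
    pd_block("dA", "c1", "P9", TRUE, c(5, 5, 5, 5), NA)  # defines 4 replicates
  )
  calls <- specificity_filter(recs)
  expect_equal(calls$avg_sc_uncompeted[calls$protein == "P1"], 2)
})

test_that("gate rejects bad input and names the offending drug", {
  recs <- pd_block("dA", "c1", "P1", TRUE, c(5, 5, 5, 5), 1)
  bad <- recs; bad$spectral_count[1] <- -1
  expect_error(specificity_filter(bad), "negative")
  only_comp <- recs[recs$competed, ]
  expect_error(specificity_filter(only_comp), "dA")
})

test_that("gate monotonicity: stricter thresholds never add specific calls", {
  for (s in 1:10) {
    cfg <- sim_config(n_proteins = 120L, n_drugs = 2L, seed = s)
    net <- generate_ppi(cfg)
    tr <- generate_truth(net, cfg)
    recs <- generate_pulldowns(net, tr, cfg)
    loose <- specificity_filter(recs, ratio_threshold = 2, min_avg_sc = 10)
    strict <- specificity_filter(recs, ratio_threshold = 3, min_avg_sc = 15)
    sp <- function(x) paste(x$drug, x$cell_type, x$protein)[
      x$verdict != "nonspecific"]
    expect_true(all(sp(strict) %in% sp(loose)))
  }
})

test_that("cross-drug absence rescues otherwise nonspecific proteins", {
  # protein PX fails the gate for dA but never appears with dB, dC, dD
  recs <- rbind(
    pd_block("dA", "c1", "PX", FALSE, c(12, 12, 12, 12), 10),
    pd_block("dA", "c1", "PY", FALSE, c(12, 12, 12, 12), 10),
    pd_block("dB", "c1", "PY", FALSE, c(6, 6, 6, 6), 6),
    pd_block("dC", "c1", "PY", FALSE, c(6, 6, 6, 6), 6),
    pd_block("dD", "c1", "PY", FALSE, c(6, 6, 6, 6), 6),
    pd_block("dB", "c1", "PZ", FALSE, c(6, 6, 6, 6), 6),
    pd_block("dB", "c1", "P0", FALSE, c(12, 12, 12, 12), 10),
    pd_block("dC", "c1", "P0", FALSE, c(6, 6, 6, 6), 6),
    pd_block("dD", "c1", "P0", FALSE, c(6, 6, 6, 6), 6)
  )
  calls <- specificity_filter(recs)
  presence <- unique(recs[!recs$competed, c("drug", "cell_type", "protein")])
  out <- rescue_by_cross_drug_absence(calls, presence, min_absent_in = 2L)
  v <- function(p, d) out$verdict[out$protein == p & out$drug == d]
  expect_identical(v("PX", "dA"), "rescued")       # absent from 3 others
  expect_identical(v("PY", "dA"), "nonspecific")   # present everywhere
  expect_identical(v("P0", "dB"), "nonspecific")   # absent in exactly 1 other
  expect_error(
    rescue_by_cross_drug_absence(calls, presence, min_absent_in = 4L),
    "min_absent_in")
})

test_that("abundance score multiplies count by coverage with kinase weighting", {
  expect_equal(abundance_score(10, 20, TRUE), 200)
  expect_equal(abundance_score(10, 20, FALSE), 50)
  expect_equal(abundance_score(0, 0, TRUE), 0)
  expect_equal(abundance_score(0, 0, FALSE), 0)
  expect_equal(abundance_score(c(10, 10), c(20, 20), c(TRUE, FALSE)),
               c(200, 50))
  expect_error(abundance_score(-1, 10, TRUE), "spectral")
  expect_error(abundance_score(1, 150, TRUE), "coverage")
})

test_that("profiles score specific proteins from replicate averages", {
  recs <- rbind(
    pd_row("dA", "c1", "R1", FALSE, "K1", TRUE, 12, 30),
    pd_row("dA", "c1", "R2", FALSE, "K1", TRUE, 12, 30),
    pd_row("dA", "c1", "R1", TRUE,  "K1", TRUE, 1, 5)
  )
  recs$replicate[3] <- "C1"
  calls <- specificity_filter(recs)
  prof <- build_profile(calls, recs, "dA")
  expect_named(prof, "c1")
  expect_equal(prof$c1$scores, c(K1 = 12 * 30))
  expect_error(build_profile(calls, recs, "nope"), "unknown drug")
})

test_that("profile assembly includes rescued proteins and matches a manual filter", {
  # five-protein fixture, computed by hand:
  #  K1 kinase: unc avg 20, comp 5  -> ratio gate, A = 20 * cov(20)
  #  N1 nonkinase: unc avg 4, absent -> absence rule, A = 4 * cov * 0.25
  #  N2 nonkinase: unc avg 12, comp 10 -> fails gate, absent in dB & dC -> rescued
  #  N3 nonkinase: unc avg 12, comp 10, present everywhere -> nonspecific
  #  K2 kinase: unc avg 0.5, absent from competition but below the lowered
  #     count threshold, and present with dB and dC so not rescued
  recs <- rbind(
    pd_block("dA", "c1", "K1", TRUE, c(20, 20, 20, 20), 5),
    pd_block("dA", "c1", "N1", FALSE, c(4, 4, 4, 4), NA),
    pd_block("dA", "c1", "N2", FALSE, c(12, 12, 12, 12), 10),
    pd_block("dA", "c1", "N3", FALSE, c(12, 12, 12, 12), 10),
    pd_block("dA", "c1", "K2", TRUE, c(2, 0, 0, 0), NA),
    pd_block("dB", "c1", "K2", TRUE, c(3, 3, 3, 3), 3),
    pd_block("dC", "c1", "K2", TRUE, c(3, 3, 3, 3), 3),
    pd_block("dB", "c1", "N3", FALSE, c(3, 3, 3, 3), 3),
    pd_block("dC", "c1", "N3", FALSE, c(3, 3, 3, 3), 3)
  )
  calls <- specificity_filter(recs)
  presence <- unique(recs[!recs$competed, c("drug", "cell_type", "protein")])
  calls <- rescue_by_cross_drug_absence(calls, presence, min_absent_in = 2L)
  prof <- build_profile(calls, recs, "dA")$c1
  cov <- function(sc) 100 * sc / (sc + 20)
  expect_setequal(names(prof$scores), c("K1", "N1", "N2"))
  expect_equal(prof$scores[["K1"]], 20 * cov(20))
  expect_equal(prof$scores[["N1"]], 4 * cov(4) * 0.25)
  expect_equal(prof$scores[["N2"]], 12 * cov(12) * 0.25)
  expect_identical(
    prof$provenance$verdict[prof$provenance$protein == "N2"], "rescued")
})

test_that("profile merging takes the per-protein maximum over cell types", {
  p1 <- drugnet:::new_target_profile("dA", c(K1 = 200, K2 = 50),
          data.frame(protein = c("K1", "K2"), cell_type = "c1",
                     A = c(200, 50), is_kinase = TRUE,
                     verdict = "specific_by_ratio"))
  p2 <- drugnet:::new_target_profile("dA", c(K1 = 150, K3 = 70),
          data.frame(protein = c("K1", "K3"), cell_type = "c2",
                     A = c(150, 70), is_kinase = TRUE,
                     verdict = "specific_by_ratio"))
  m <- merge_profiles(list(p1, p2))
  expect_equal(m$scores, c(K1 = 200, K2 = 50, K3 = 70))
  expect_identical(
    m$provenance$cell_type[m$provenance$protein == "K1"], "c1")
  # idempotent, commutative, associative
  expect_equal(merge_profiles(list(p1, p1))$scores, p1$scores)
  expect_equal(merge_profiles(list(p2, p1))$scores, m$scores)
  p3 <- drugnet:::new_target_profile("dA", c(K2 = 60),
          data.frame(protein = "K2", cell_type = "c3", A = 60,
                     is_kinase = TRUE, verdict = "specific_by_ratio"))
  expect_equal(
    merge_profiles(list(merge_profiles(list(p1, p2)), p3))$scores,
    merge_profiles(list(p1, merge_profiles(list(p2, p3))))$scores)
  bad <- drugnet:::new_target_profile("dB", c(K1 = 1),
          data.frame(protein = "K1", cell_type = "c1", A = 1,
                     is_kinase = TRUE, verdict = "specific_by_ratio"))
  expect_error(merge_profiles(list(p1, bad)), "different drugs")
})

test_that("one-sided KS statistic and asymptotic tail match hand calculations", {
  ks <- ks_specificity_pvalue(rep(100, 8), rep(0, 24))
  expect_equal(ks$D, 1)
  expect_equal(ks$p, exp(-12))
  ks2 <- ks_specificity_pvalue(c(30, 40), rep(0, 8))
  expect_equal(ks2$p, exp(-3.2))
  same <- ks_specificity_pvalue(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  # 5 positive of 8 values against 24 zeros: D = 5/8
  a <- c(10, 20, 30, 40, 50, 0, 0, 0)
  ks3 <- ks_specificity_pvalue(a, rep(0, 24))
  expect_equal(ks3$D, 5 / 8)
  expect_equal(ks3$D, ks_D_bruteforce(a, rep(0, 24)))
  expect_equal(ks3$p, exp(-2 * (5 / 8)^2 * 8 * 24 / 32))
  expect_error(ks_specificity_pvalue(numeric(0), 1), "non-empty")
})

test_that("KS statistic agrees with the brute-force ECDF scan on random data", {
  set.seed(31)
  for (i in 1:25) {
    a <- round(rgamma(sample(2:10, 1), 2, 0.1))
    b <- round(rgamma(sample(2:30, 1), 2, 0.2))
    expect_equal(ks_specificity_pvalue(a, b)$D, ks_D_bruteforce(a, b))
  }
})

test_that("KS p decreases in D and is scale invariant", {
  n <- 8; m <- 24
  p_of_D <- function(k) {  # k positive values of n, rest zero, vs m zeros
    a <- c(rep(10, k), rep(0, n - k))
    ks_specificity_pvalue(a, rep(0, m))$p
  }
  ps <- vapply(1:n, p_of_D, numeric(1))
  expect_true(all(diff(ps) < 0))
  a <- c(5, 9, 14, 0); b <- c(1, 2, 0, 0, 0)
  expect_equal(ks_specificity_pvalue(a, b)$p,
               ks_specificity_pvalue(7.3 * a, 7.3 * b)$p)
})

test_that("exact KS option gives the permutation tail for complete separation", {
  a <- rep(100, 4); b <- rep(0, 4)
  asym <- ks_specificity_pvalue(a, b)$p
  exact <- ks_specificity_pvalue(a, b, method = "exact")$p
  # complete separation of 4 vs 4: exactly one of the C(8, 4) group
  # assignments reaches D = 1, while the asymptotic tail is exp(-4)
  expect_equal(exact, 1 / choose(8, 4))
  expect_equal(asym, exp(-4))
})
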