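# The FHB / FHC / FastFHC smoothing strategies and DMR reporting.

test_that("binarization thresholds the FDR strictly", {
  expect_equal(binarize_fdr(c(0.2, 0.01, 0.04), 0.05), c(0L, 1L, 1L))
  expect_equal(binarize_fdr(c(0.3, 0.9), 1 - 1e-9), c(1L, 1L))
  expect_equal(binarize_fdr(1, 0.05), 0L)  # degenerate bins never called
  expect_error(binarize_fdr(0.5, 0), "0, 1")
})

test_that("p-value emission matrix has the (p, 1-p) structure with clipping", {
  expect_equal(build_emission_from_pvalues(0.5), cbind(0.5, 0.5))
  expect_equal(build_emission_from_pvalues(1), cbind(1 - 1e-10, 1e-10))
  expect_equal(build_emission_from_pvalues(c(0.01, 0.99)),
               cbind(c(0.01, 0.99), c(0.99, 0.01)))
  expect_error(build_emission_from_pvalues(0), "0, 1")
})

test_that("FHB recovers a run of differential bins and falls back on short sites", {
  sizes <- balanced_sizes()
  # 12-bin site, strong treated-IP gain on bins 5..8
  y1 <- rep(100L, 12)
  y1[5:8] <- 800L
  fit <- run_fhb(make_site_counts(y1), sizes, seed = 1)
  expect_true(all(fit$bins$posterior[5:8] >= 0.5))
  expect_true(all(fit$bins$posterior[c(1, 2, 11, 12)] < 0.5))
  expect_false(any(fit$bins$em_fallback))

  # all-null observations: differential state never favoured
  fit0 <- run_fhb(make_site_counts(rep(100L, 10)), sizes, seed = 1)
  expect_true(all(fit0$bins$posterior <= 0.5 + 1e-9))

  # site shorter than min_bins_for_em: 1 - p surrogate, flagged
  short <- make_site_counts(c(100L, 800L, 100L))
  fit_s <- run_fhb(short, sizes, seed = 1)
  expect_true(all(fit_s$bins$em_fallback))
  expect_equal(fit_s$bins$posterior, 1 - fit_s$bins$p_value)
})

test_that("FHB and FastFHC ignore p-value changes that do not cross the threshold", {
  res <- data.frame(site_id = "s1", bin_index = 0:7,
                    p_value = c(0.9, 0.8, 1e-5, 1e-6, 1e-5, 0.7, 0.6, 0.9))
  res$fdr <- bh_fdr(res$p_value)
  res2 <- res
  res2$p_value <- c(0.95, 0.7, 1e-4, 1e-4, 1e-4, 0.75, 0.65, 0.85)
  res2$fdr <- bh_fdr(res2$p_value)
  expect_identical(binarize_fdr(res$fdr, 0.05), binarize_fdr(res2$fdr, 0.05))

  set.seed(4)
  p1 <- fethmm:::.em_strategy(res, "fhb")$bins$posterior
  set.seed(4)
  p2 <- fethmm:::.em_strategy(res2, "fhb")$bins$posterior
  expect_identical(p1, p2)

  # FHC is continuous in the p-values instead: small perturbations move
  # the posterior, but only slightly
  set.seed(4)
  f1 <- fethmm:::.em_strategy(res, "fhc")$bins$posterior
  res3 <- res
  res3$p_value <- pmin(1, res$p_value * 1.01)
  set.seed(4)
  f3 <- fethmm:::.em_strategy(res3, "fhc")$bins$posterior
  expect_false(identical(f1, f3))
  expect_lt(max(abs(f1 - f3)), 0.05)
})

test_that("FHC smooths continuous significance and matches enumeration", {
  sizes <- balanced_sizes()
  # uninformative p-values: the posterior is the bare chain marginal,
  # constant when the start distribution is stationary for A
  flat_emis <- build_emission_from_pvalues(rep(0.5, 10))
  fit_flat <- baum_welch(emission = flat_emis,
                         init = list(pi = c(0.5, 0.5),
                                     A = matrix(c(0.8, 0.2, 0.2, 0.8), 2,
                                                byrow = TRUE)))
  expect_equal(fit_flat$posterior, rep(0.5, 10), tolerance = 1e-9)

  # strong evidence everywhere drives the posterior to 1
  strong <- make_site_counts(rep(900L, 8))
  fit <- run_fhc(strong, sizes, seed = 3)
  expect_true(all(fit$bins$posterior > 0.95))

  # converged parameters reproduce the brute-force posterior exactly
  counts <- make_site_counts(c(100L, 130L, 700L, 650L, 100L, 90L, 120L, 700L))
  fit <- run_fhc(counts, sizes, seed = 5)
  prm <- fit$params[[1]]
  emis <- fethmm::build_emission_from_pvalues(fit$bins$p_value)
  oracle <- enum_posterior(prm$pi, prm$A, fethmm::clip_emission(emis))
  expect_equal(fit$bins$posterior, oracle$gamma[, 2], tolerance = 1e-8)
})

test_that("pooled parameter estimation counts within-site transitions", {
  # hand count: transitions 0->0, 0->1, 1->1
  prm <- estimate_pooled_params(list(c(0L, 0L, 1L, 1L)), pseudocount = 0)
  expect_equal(prm$pi, c(0.5, 0.5))
  expect_equal(prm$A, matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE))

  # all-null genome: degenerate pi but proper smoothed transitions
  prm <- estimate_pooled_params(list(rep(0L, 10)), pseudocount = 1)
  expect_equal(prm$pi, c(1, 0))
  expect_equal(rowSums(prm$A), c(1, 1))
  expect_equal(prm$A[2, ], c(0.5, 0.5))

  # single-bin sites contribute no transitions
  prm <- estimate_pooled_params(list(0L, 1L, 1L), pseudocount = 1)
  expect_equal(prm$pi, c(1 / 3, 2 / 3))
  expect_equal(prm$A, matrix(0.5, 2, 2))

  # site boundaries never contribute: two sites vs their concatenation
  a <- estimate_pooled_params(list(c(0L, 1L), c(1L, 0L)), pseudocount = 0)
  b <- estimate_pooled_params(list(c(0L, 1L, 1L, 0L)), pseudocount = 0)
  expect_false(identical(a$A, b$A))

  expect_error(estimate_pooled_params(list()), "no bins")
})

test_that("FastFHC equals a pooled-parameter E-step and is deterministic", {
  sizes <- balanced_sizes()
  counts <- make_site_counts(c(100L, 120L, 750L, 700L, 100L, 95L, 105L, 720L))
  fit <- run_fastfhc(counts, sizes)
  res <- test_bins(counts, sizes)
  pooled <- estimate_pooled_params(list(binarize_fdr(res$fdr, 0.05)))
  direct <- estep_only(pooled$pi, pooled$A,
                       build_emission_from_pvalues(res$p_value))
  expect_equal(fit$bins$posterior, direct$posterior)
  expect_equal(fit$params, pooled)

  # enumeration oracle at the pooled parameters
  oracle <- enum_posterior(pooled$pi, pooled$A,
                           build_emission_from_pvalues(res$p_value))
  expect_equal(fit$bins$posterior, oracle$gamma[, 2], tolerance = 1e-8)

  # two identical sites give identical posterior tracks
  two <- rbind(counts, transform(counts, site_id = "s2"))
  fit2 <- run_fastfhc(two, sizes)
  expect_equal(fit2$bins$posterior[1:8], fit2$bins$posterior[9:16])
})

test_that("DMR calling merges runs within sites", {
  bins <- data.frame(site_id = "s1", bin_index = 0:3,
                     posterior = c(0.95, 0.96, 0.1, 0.92),
                     p_value = c(1e-4, 1e-5, 0.6, 1e-3),
                     log2_or = c(1.2, 1.5, 0.1, -2))
  dmrs <- call_dmrs(bins, cutoff = 0.9)
  expect_equal(nrow(dmrs), 2L)
  expect_equal(dmrs$bin_start, c(0L, 3L))
  expect_equal(dmrs$bin_end, c(1L, 3L))
  expect_equal(dmrs$direction, c("hyper", "hypo"))
  expect_equal(dmrs$best_p, c(1e-5, 1e-3))

  expect_equal(nrow(call_dmrs(transform(bins, posterior = 0.1))), 0L)

  # near-zero cutoff spans each whole site
  all_in <- call_dmrs(bins, cutoff = 1e-9)
  expect_equal(nrow(all_in), 1L)
  expect_equal(all_in$n_bins, 4L)

  # runs never merge across site boundaries
  two <- rbind(bins, transform(bins, site_id = "s2"))
  two$posterior <- 0.95
  dmrs2 <- call_dmrs(two, cutoff = 0.9)
  expect_equal(nrow(dmrs2), 2L)
  expect_equal(dmrs2$site_id, c("s1", "s2"))
})

test_that("detect_dmrs dispatches and attaches DMR calls", {
  sizes <- balanced_sizes()
  counts <- make_site_counts(c(rep(100L, 4), rep(800L, 4), rep(100L, 4)))
  out <- detect_dmrs(counts, sizes, strategy = "fastfhc",
                     posterior_cutoff = 0.9)
  expect_true(all(c("bins", "params", "dmrs") %in% names(out)))
  expect_gte(nrow(out$dmrs), 1L)
  expect_true(all(out$dmrs$bin_start >= 4 - 1))
})
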