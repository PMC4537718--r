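# Library rescaling, the two-tailed rescaled hypergeometric test, BH
# adjustment and the per-bin testing pipeline.

test_that("rescaling balances the treated IP library and only it", {
  counts <- data.frame(x0 = c(10, 3), y0 = c(7, 0), x1 = c(4, 9),
                       y1 = c(40, 0))

  # already balanced: nothing changes
  r <- rescale_counts(counts, lib_sizes(1e8, 1e8, 1e8, 1e8))
  expect_identical(r$counts, counts)
  expect_equal(r$rho, 1)

  # treated IP twice as deep: y1 halved, effective M1 back to 1e8
  r <- rescale_counts(counts, lib_sizes(1e8, 1e8, 1e8, 2e8))
  expect_equal(r$rho, 2)
  expect_equal(r$counts$y1, c(20, 0))
  expect_equal(unname(r$sizes[["m1"]]), 1e8)
  expect_equal(r$counts[c("x0", "y0", "x1")], counts[c("x0", "y0", "x1")])
  # balance identity holds exactly on the effective sizes
  expect_identical(r$sizes[["n1"]] * r$sizes[["m0"]],
                   r$sizes[["n0"]] * r$sizes[["m1"]])

  # zero counts stay zero under any imbalance
  r <- rescale_counts(data.frame(x0 = 1, y0 = 1, x1 = 1, y1 = 0),
                      lib_sizes(3e7, 1e8, 2e8, 5e7))
  expect_equal(r$counts$y1, 0)

  expect_error(lib_sizes(0, 1e8, 1e8, 1e8), "positive")
  expect_error(rescale_counts(counts, c(1e8, -1, 1e8, 1e8)), "positive")
})

test_that("two-tailed p-values match the exact-test oracle", {
  # perfectly balanced table
  expect_equal(rhtest(5, 5, 5, 5), 1)
  # empty table is degenerate
  expect_equal(rhtest(0, 0, 0, 0), 1)

  # direct enumeration for a small table: sum of hypergeometric masses
  # not exceeding the observed one, over k in 0..4
  d <- dhyper(0:4, 4, 4, 4)
  p_expected <- sum(d[d <= d[4] * (1 + 1e-7)])
  expect_equal(rhtest(3, 1, 1, 3), p_expected, tolerance = 1e-14)

  # agreement with fisher.test on random tables
  set.seed(42)
  for (i in 1:200) {
    x <- rpois(4, lambda = sample(c(2, 10, 40), 1))
    p_ref <- stats::fisher.test(matrix(c(x[1], x[2], x[3], x[4]), 2,
                                       byrow = TRUE))$p.value
    expect_equal(rhtest(x[1], x[2], x[3], x[4]), min(1, p_ref),
                 tolerance = 1e-12)
  }
})

test_that("p-values are invariant to depth scaling and condition swap", {
  counts <- data.frame(x0 = 30, y0 = 12, x1 = 25, y1 = 44)
  s1 <- lib_sizes(1e8, 2e8, 5e7, 1e8)
  s2 <- lib_sizes(3e8, 6e8, 1.5e8, 3e8)  # same ratios, 3x depth
  expect_equal(test_bins(cbind(site_id = "s", bin_index = 0L, counts), s1)$p_value,
               test_bins(cbind(site_id = "s", bin_index = 0L, counts), s2)$p_value)

  # balanced libraries: swapping conditions leaves the two-tailed p unchanged
  expect_equal(rhtest(30, 12, 25, 44), rhtest(25, 44, 30, 12))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # hand-computed step-up: p * n/rank, monotone from the largest down
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("test_bins preserves order and flags degenerate bins", {
  sizes <- balanced_sizes()

  empty <- data.frame(site_id = rep(c("a", "b"), each = 5),
                      bin_index = rep(0:4, 2),
                      x0 = 0L, y0 = 0L, x1 = 0L, y1 = 0L)
  res <- test_bins(empty, sizes)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$fdr == 1))
  expect_true(all(res$degenerate))
  expect_equal(res$log2_or, rep(0, 10))

  # one strong treated-IP gain: smallest p in its site, positive direction
  counts <- make_site_counts(c(100, 100, 800, 100, 100))
  res <- test_bins(counts, sizes)
  expect_equal(which.min(res$p_value), 3L)
  expect_gt(res$log2_or[3], 0)
  expect_identical(res$site_id, counts$site_id)
  expect_identical(res$bin_index, counts$bin_index)

  # single bin reduces to the plain exact test (FDR = p)
  one <- make_site_counts(250)
  res <- test_bins(one, sizes)
  expect_equal(res$p_value, rhtest(100, 100, 100, 250))
  expect_equal(res$fdr, res$p_value)
})

test_that("empirical type-I error under the null is controlled", {
  cfg <- sim_config(n_sites = 5, bins_per_site = 400,
                    dm_log2or_range = c(0, 0),
                    de_log2fc_range = c(0, 0))
  d <- simulate_dataset(cfg, seed = 99)
  res <- test_bins(d$counts, cfg$lib_sizes)
  n <- nrow(res)
  rate <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(rate, 0.05 + 3 * se)
})
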