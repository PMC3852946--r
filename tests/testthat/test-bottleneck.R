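test_that("fixed-threshold M test uses a strict 0.68 inequality", {
  # 17 occupied states in a 25-state range -> M exactly 0.68
  states <- c(10:25, 34L)
  geno <- matrix(rep(states, each = 2), nrow = 17, ncol = 2, byrow = TRUE)
  ds <- make_ms_dataset(geno)
  expect_equal(summary_stats(ds)$m, 0.68)
  expect_false(m_ratio_ft_test(ds)$call)
  # one fewer occupied state in the same range -> below threshold
  geno2 <- geno; geno2[geno2 == 25L] <- 10L
  ds2 <- make_ms_dataset(geno2)
  expect_lt(summary_stats(ds2)$m, 0.68)
  expect_true(m_ratio_ft_test(ds2)$call)
  # contiguous alleles -> M = 1 -> never called
  ds3 <- make_ms_dataset(matrix(sample(10:13, 40, TRUE), ncol = 2))
  expect_false(m_ratio_ft_test(ds3)$call)
})

test_that("simulated-critical-value M test is deterministic and edge-safe", {
  ds_mono <- make_ms_dataset(matrix(12L, nrow = 10, ncol = 4))
  # M = 1 can never fall strictly below a critical value <= 1
  r <- m_ratio_sim_test(ds_mono, true_ne = 500, true_mu = 5e-4,
                        n_sims = 100, seed = 4)
  expect_false(r$call)
  expect_lte(r$critical_value, 1)
  # degenerate null (all mass at 1): called only when observed M < 1
  null1 <- rep(1, 100)
  ds_gap <- make_ms_dataset(matrix(c(10L, 10L, 10L, 12L), nrow = 2,
                                   byrow = TRUE))
  expect_true(m_ratio_sim_test(ds_gap, 500, 5e-4, null_M = null1)$call)
  expect_false(m_ratio_sim_test(ds_mono, 500, 5e-4, null_M = null1)$call)
  # same dataset, same seed -> identical call
  a <- m_ratio_sim_test(ds_gap, 500, 5e-4, n_sims = 50, seed = 9)
  b <- m_ratio_sim_test(ds_gap, 500, 5e-4, n_sims = 50, seed = 9)
  expect_identical(a, b)
})

test_that("signed-rank wrapper matches exact enumeration for n <= 10", {
  set.seed(19)
  for (n in c(5, 7, 10)) {
    for (rep in 1:5) {
      x <- round(rnorm(n), 4)
      while (any(duplicated(abs(x))) || any(x == 0)) x <- round(rnorm(n), 4)
      expect_equal(srsfpr:::signed_rank_p(x), oracle_signed_rank_p(x),
                   tolerance = 1e-12)
    }
  }
  expect_equal(srsfpr:::signed_rank_p(numeric(0)), 1)
  expect_equal(srsfpr:::signed_rank_p(c(0, 0, 0)), 1)
})

test_that("heterozygosity-excess test calls uniform excess and skips sparse data", {
  # 15 two-allele loci near 50/50: He ~ 0.5 far above Heq given k = 2
  set.seed(21)
  n <- 50
  geno <- matrix(0L, nrow = n, ncol = 30)
  for (l in 1:15) {
    n1 <- 50 - l  # distinct minor-allele frequency per locus (no rank ties)
    copies <- sample(c(rep(10L, n1), rep(11L, 2 * n - n1)))
    geno[, 2 * l - 1] <- copies[1:n]
    geno[, 2 * l] <- copies[(n + 1):(2 * n)]
  }
  ds <- make_ms_dataset(geno)
  r <- het_excess_test(ds, min_accepted = 300)
  expect_true(r$applicable)
  expect_true(all(r$loci$delta > 0))
  expect_equal(r$p, 2^-15, tolerance = 1e-10)
  expect_true(r$call)

  # fewer than 4 polymorphic loci: not applicable, no call
  geno2 <- matrix(12L, nrow = 10, ncol = 30)
  geno2[1, c(1, 3, 5)] <- 13L
  r2 <- het_excess_test(make_ms_dataset(geno2))
  expect_false(r2$applicable)
  expect_false(r2$call)
})

test_that("Tajima test handles S = 0 and is deterministic given a seed", {
  ds0 <- make_seq_dataset(matrix(0L, nrow = 20, ncol = 50))
  r0 <- tajima_test(ds0)
  expect_false(r0$applicable)
  expect_false(r0$call)

  set.seed(22)
  mat <- drop_mutations(simulate_genealogy(20), 2, "infinite_sites")
  ds <- make_seq_dataset(mat)
  a <- tajima_test(ds, n_sims = 200, seed = 5)
  b <- tajima_test(ds, n_sims = 200, seed = 5)
  expect_identical(a, b)
  expect_gte(a$p, 0); expect_lte(a$p, 1)
})

test_that("the battery dispatches on marker type", {
  set.seed(25)
  geno <- matrix(sample(10:14, 200, TRUE), ncol = 4)
  ds <- make_ms_dataset(geno)
  bt <- test_battery(ds, true_ne = 50, true_mu = 5e-4,
                     tests = c("m_ratio_ft", "het_excess"))
  expect_named(bt, c("m_ratio_ft", "het_excess"))
  mat <- matrix(rbinom(40 * 20, 1, 0.2), nrow = 40)
  bt2 <- test_battery(make_seq_dataset(mat))
  expect_named(bt2, "tajima")
})
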