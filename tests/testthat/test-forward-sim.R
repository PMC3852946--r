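test_that("initialization respects allele count and determinism", {
  cfg <- demography_config(20, 2, n_loci = 4, sample_size = 10)
  mono <- initialize_population(cfg, n_init_alleles = 1)
  ss <- summary_stats(sample_individuals(mono, 10))
  expect_equal(ss$he, 0)
  expect_equal(ss$k, 1)

  set.seed(33); p1 <- initialize_population(cfg, n_init_alleles = 10,
                                            dirichlet_conc = 1)
  set.seed(33); p2 <- initialize_population(cfg, n_init_alleles = 10,
                                            dirichlet_conc = 1)
  expect_identical(p1$geno, p2$geno)
  expect_lte(max(apply(p1$geno, 2, function(x) length(unique(x)))), 10)
})

test_that("census size is constant every generation", {
  for (vk in c(2, 400)) {
    cfg <- demography_config(10, vk, n_loci = 3, sample_size = 5)
    model <- offspring_model(vk)
    set.seed(40 + vk)
    pop <- initialize_population(cfg)
    for (g in 1:10) {
      pop <- advance_generation(pop, model)
      expect_equal(nrow(pop$geno), cfg$nc)
    }
  }
})

test_that("no mutation and no variation stay frozen", {
  cfg <- demography_config(20, 2, n_loci = 3, sample_size = 10)
  model <- offspring_model(2)
  set.seed(41)
  pop <- initialize_population(cfg, n_init_alleles = 1)
  pop2 <- advance_generation(pop, model, mu = 0)
  expect_identical(sort(unique(as.vector(pop2$geno))),
                   sort(unique(as.vector(pop$geno))))
})

test_that("per-parent offspring counts at Vk=2 are Poisson(2)", {
  nc <- 100000L
  cfg <- demography_config(nc, 2, n_loci = 1, sample_size = 10)
  stopifnot(cfg$nc == nc)
  # identifiable parents: individual i carries alleles (2i, 2i+1)
  pop <- initialize_population(cfg, n_init_alleles = 1)
  pop$geno[, 1] <- 2L * seq_len(nc)
  pop$geno[, 2] <- 2L * seq_len(nc) + 1L
  set.seed(44)
  pop2 <- advance_generation(pop, offspring_model(2), mu = 0)
  parents <- c(pop2$geno[, 1] %/% 2L, pop2$geno[, 2] %/% 2L)
  counts <- tabulate(parents, nbins = nc)
  expect_equal(mean(counts), 2)
  cap <- 8
  obs <- tabulate(pmin(counts, cap) + 1L, nbins = cap + 1L)
  p <- dpois(0:(cap - 1), 2); p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("sweepstakes generations funnel through few distinct parents", {
  vk <- 2000
  nc <- 1000L
  model <- offspring_model(vk)
  cfg <- demography_config(nc * 4 / (vk + 2), vk, n_loci = 1, sample_size = 5)
  stopifnot(cfg$nc == nc)
  set.seed(45)
  distinct <- replicate(200, {
    pop <- initialize_population(cfg, n_init_alleles = 1)
    pop$geno[, 1] <- 2L * seq_len(nc)
    pop$geno[, 2] <- 2L * seq_len(nc) + 1L
    pop2 <- advance_generation(pop, model, mu = 0)
    length(unique(c(pop2$geno[, 1] %/% 2L, pop2$geno[, 2] %/% 2L)))
  })
  want <- oracle_distinct_parents(model, nc, 200)
  expect_lt(mean(distinct), 0.2 * nc)        # high sib fraction
  expect_lt(abs(mean(distinct) - want),
            3 * sd(distinct) / sqrt(200) + 3 * want / sqrt(200))
})

test_that("realized per-parent variance tracks the target Vk", {
  nc <- 50000L
  vk <- 400
  cfg <- demography_config(nc * 4 / (vk + 2), vk, n_loci = 1, sample_size = 5)
  pop <- initialize_population(cfg, n_init_alleles = 1)
  pop$geno[, 1] <- 2L * seq_len(nc)
  pop$geno[, 2] <- 2L * seq_len(nc) + 1L
  set.seed(46)
  pop2 <- advance_generation(pop, offspring_model(vk), mu = 0)
  counts <- tabulate(c(pop2$geno[, 1] %/% 2L, pop2$geno[, 2] %/% 2L),
                     nbins = nc)
  expect_gt(var(counts), 0.6 * vk)
  expect_lt(var(counts), 1.5 * vk)
})

test_that("constrained loci stay inside the 5-state window", {
  cfg <- demography_config(20, 40, n_loci = 4, sample_size = 10,
                           marker_type = "microsat_constrained")
  model <- offspring_model(40)
  set.seed(47)
  pop <- initialize_population(cfg)
  for (g in 1:60) pop <- advance_generation(pop, model, mu = 0.05)
  expect_true(all(pop$geno >= 18L & pop$geno <= 22L))
  expect_gt(length(unique(as.vector(pop$geno))), 1)  # mutation was active
})

test_that("pure drift never increases heterozygosity on average", {
  cfg <- demography_config(10, 2, n_loci = 1, sample_size = 5)
  model <- offspring_model(2)
  set.seed(48)
  dropped <- replicate(100, {
    pop <- initialize_population(cfg, n_init_alleles = 2, dirichlet_conc = 5)
    he0 <- srsfpr:::pop_diagnostics(pop)[["He"]]
    for (g in 1:60) pop <- advance_generation(pop, model, mu = 0)
    srsfpr:::pop_diagnostics(pop)[["He"]] <= he0
  })
  expect_gte(mean(dropped), 0.95)
})

test_that("burn-in 0 is the identity and diagnostics are recorded", {
  cfg <- demography_config(20, 2, n_loci = 3, sample_size = 10)
  set.seed(49)
  pop <- initialize_population(cfg)
  eq0 <- run_to_equilibrium(cfg, burnin_generations = 0, pop = pop)
  expect_identical(eq0$population$geno, pop$geno)
  eq <- run_to_equilibrium(cfg, burnin_generations = 40, check_interval = 10,
                           pop = pop)
  expect_equal(nrow(eq$diagnostics), 4)
  expect_equal(eq$population$generation, 40L)
})

test_that("sampling is uniform-without-replacement and validated", {
  cfg <- demography_config(20, 2, n_loci = 2, sample_size = 10)
  set.seed(50)
  pop <- initialize_population(cfg)
  expect_error(sample_individuals(pop, 21), "cannot sample")
  all_of_them <- sample_individuals(pop, 20)
  expect_equal(sort(as.vector(all_of_them$genotypes[, 1])),
               sort(as.vector(pop$geno[, 1])))
  set.seed(51); s1 <- sample_individuals(pop, 10)
  set.seed(51); s2 <- sample_individuals(pop, 10)
  expect_identical(s1$genotypes, s2$genotypes)
})

test_that("sequence mode keeps the infinite-sites bookkeeping consistent", {
  cfg <- demography_config(20, 2, marker_type = "sequence", n_sites = 50,
                           sample_size = 10, mu = 1e-4)
  model <- offspring_model(2)
  set.seed(52)
  pop <- initialize_population(cfg)
  for (g in 1:200) pop <- advance_generation(pop, model)
  ds <- sample_individuals(pop, 10)
  expect_equal(dim(ds$seq), c(20, 50))
  d <- colSums(ds$seq)
  expect_true(all(d >= 0 & d <= 20))
  # an over-saturated locus errors out instead of violating infinite sites
  cfg2 <- demography_config(20, 2, marker_type = "sequence", n_sites = 3,
                            sample_size = 10, mu = 0.25)
  set.seed(53)
  pop2 <- initialize_population(cfg2)
  expect_error({
    for (g in 1:50) pop2 <- advance_generation(pop2, model)
  }, "infinite-sites")
})

test_that("two runs from one seed are identical end to end", {
  cfg <- demography_config(30, 40, n_loci = 5, sample_size = 15)
  ds1 <- simulate_dataset(cfg, seed = 99, burnin_generations = 20)
  ds2 <- simulate_dataset(cfg, seed = 99, burnin_generations = 20)
  expect_identical(ds1$genotypes, ds2$genotypes)
})
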