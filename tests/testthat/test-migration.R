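# short diverged 3-population fixture for sampler tests
mig_fixture <- function(tm = NULL, n_per = 20, seed = 71, n_gen = 20) {
  if (is.null(tm)) tm <- matrix(0, 3, 3)
  cfg <- sim_config(n_populations = 3, n_individuals_per_pop = n_per,
                    n_loci = 10, n_alleles_per_locus = c(6, 10),
                    n_generations = n_gen, pop_sizes = 200,
                    true_migration_matrix = tm, migrant_sampling = TRUE,
                    behaviour_fraction_migratory = 0,
                    behaviour_fraction_sedentary = 0, rng_seed = seed)
  simulate_genotypes(cfg)$genotypes
}

test_that("gene-flow classification reproduces the printed thresholds", {
  expect_equal(classify_gene_flow(0.001), "low")
  expect_equal(classify_gene_flow(0.0299), "low")
  expect_equal(classify_gene_flow(0.030), "moderate")
  expect_equal(classify_gene_flow(0.05), "moderate")
  expect_equal(classify_gene_flow(0.100), "moderate")
  expect_equal(classify_gene_flow(0.1001), "high")
  expect_equal(classify_gene_flow(0.225), "high")
  expect_error(classify_gene_flow(-0.1), "\\[0, 1\\]")
  expect_error(classify_gene_flow(1.1), "\\[0, 1\\]")
})

test_that("net emigration: symmetric matrices give 0, toys match hand sums", {
  m <- matrix(c(0.9, 0.05, 0.05,
                0.05, 0.9, 0.05,
                0.05, 0.05, 0.9), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  for (p in c("A", "B", "C")) expect_equal(net_emigration(m, p), 0)
  # hand-set rates: into A from B 0.10, into B from A 0.02, others 0.01
  m2 <- matrix(c(0.88, 0.10, 0.02,
                 0.02, 0.97, 0.01,
                 0.01, 0.01, 0.98), 3, 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # outgoing(A) = m[B,A] + m[C,A] = 0.02 + 0.01; incoming(A) = 0.10 + 0.02
  expect_equal(net_emigration(m2, "A"), 0.03 - 0.12)
  expect_equal(net_emigration(m2, "B"), (0.10 + 0.01) - (0.02 + 0.01))
  tot <- sum(vapply(c("A", "B", "C"), function(p) net_emigration(m2, p),
                    numeric(1)))
  expect_equal(tot, 0)
  expect_error(net_emigration(m2, "Z"), "unknown population")
})

test_that("the sampler validates its inputs", {
  g1 <- random_genotypes(n = 6, n_pops = 1, seed = 1)
  expect_error(run_bayesass(g1, mcmc_config(n_iter = 100, burn_in = 10,
                                            thin = 1, n_chains = 1)),
               "at least 2 populations")
  expect_error(mcmc_config(n_iter = 100, burn_in = 200), "burn_in")
  expect_error(mcmc_config(delta_m = 1.5), "delta")
})

test_that("seed-fixed runs are bit-reproducible and satisfy the 1/3 constraint", {
  g <- mig_fixture()
  cfg <- mcmc_config(n_iter = 8000, burn_in = 2000, thin = 10, n_chains = 2,
                     seed = 5)
  f1 <- run_bayesass(g, cfg)
  f2 <- run_bayesass(g, cfg)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$mean, f2$mean)
  # every thinned sample satisfies the constrained simplex
  K <- 3
  for (s in seq_len(nrow(f1$samples))) {
    mm <- matrix(f1$samples[s, ], K, K, byrow = TRUE)
    expect_true(all(diag(mm) >= 2 / 3 - 1e-9))
    expect_true(all(abs(rowSums(mm) - 1) < 1e-9))
  }
  expect_true(all(f1$ci_low <= f1$mean + 1e-12))
  expect_true(all(f1$mean <= f1$ci_high + 1e-12))
})

test_that("with no usable loci the posterior reproduces the constrained prior", {
  # all genotypes missing: the likelihood is flat, so off-diagonal means must
  # match the mean of a uniform draw over {m >= 0, sum(m) <= 1/3}, i.e. 1/9
  # per entry for K = 3
  df <- tibble::tibble(individual_id = sprintf("i%d", 1:12),
                       population_id = rep(c("a", "b", "c"), each = 4),
                       l1_a1 = NA_integer_, l1_a2 = NA_integer_)
  g <- genotype_table(df)
  fit <- run_bayesass(g, mcmc_config(n_iter = 150000, burn_in = 20000,
                                     thin = 20, n_chains = 2, delta_m = 0.2,
                                     seed = 9))
  off <- fit$mean[row(fit$mean) != col(fit$mean)]
  # oracle: direct Monte Carlo from the prior by rejection
  set.seed(42)
  draws <- matrix(runif(2e5, 0, 1 / 3), ncol = 2)
  draws <- draws[rowSums(draws) <= 1 / 3, ]
  prior_mean <- mean(draws)
  expect_equal(mean(off), prior_mean, tolerance = 0.015)
  expect_equal(prior_mean, 1 / 9, tolerance = 0.005)
})

test_that("strongly diverged no-migration data give near-zero estimates", {
  g <- mig_fixture(tm = matrix(0, 3, 3), n_per = 30, seed = 13, n_gen = 30)
  fit <- run_bayesass(g, mcmc_config(n_iter = 60000, burn_in = 20000,
                                     thin = 40, n_chains = 2, seed = 3))
  off <- fit$mean[row(fit$mean) != col(fit$mean)]
  expect_true(all(off < 0.05))
  expect_true(all(diag(fit$mean) > 0.9))
})

test_that("delta tuning moves acceptance toward the 40-60% window", {
  g <- mig_fixture(n_per = 10, seed = 3, n_gen = 10)
  start <- mcmc_config(n_iter = 4000, burn_in = 1000, thin = 10, n_chains = 1,
                       delta_p = 0.01, delta_F = 0.01, delta_m = 0.005,
                       seed = 11)
  pilot0 <- suppressWarnings(run_bayesass(g, mcmc_config(
    n_iter = 4000, burn_in = 1000, thin = 10, n_chains = 1,
    delta_p = 0.01, delta_F = 0.01, delta_m = 0.005, seed = 11)))
  tuned <- tune_deltas(g, start, pilot_iter = 6000, max_rounds = 12)
  # tiny deltas over-accept, so tuning must widen them
  if (pilot0$acceptance[["F"]] > 0.6) expect_gt(tuned$delta_F, 0.01)
  if (pilot0$acceptance[["p"]] > 0.6) expect_gt(tuned$delta_p, 0.01)
  acc <- attr(tuned, "acceptance")
  expect_true(all(acc >= 0.25 & acc <= 0.75, na.rm = TRUE))
})

test_that("migration recovery: a planted 0.20 rate is found with its CI", {
  tm <- matrix(0, 3, 3)
  tm[1, 2] <- 0.20; tm[1, 3] <- 0.05
  tm[2, 1] <- 0.05; tm[2, 3] <- 0.05
  tm[3, 1] <- 0.05; tm[3, 2] <- 0.05
  cfg <- sim_config(n_populations = 3, n_individuals_per_pop = 50,
                    n_loci = 14, n_alleles_per_locus = c(5, 15),
                    n_generations = 30, pop_sizes = 200,
                    true_migration_matrix = tm, migrant_sampling = TRUE,
                    behaviour_fraction_migratory = 0,
                    behaviour_fraction_sedentary = 0, rng_seed = 2024)
  g <- simulate_genotypes(cfg)$genotypes
  fit <- run_bayesass(g, mcmc_config(n_iter = 100000, burn_in = 30000,
                                     thin = 50, n_chains = 2, seed = 17))
  expect_lt(abs(fit$mean["pop1", "pop2"] - 0.20), 0.10)
  expect_lte(fit$ci_low["pop1", "pop2"], 0.20)
  expect_gte(fit$ci_high["pop1", "pop2"], 0.20)
  expect_equal(fit$class["pop1", "pop2"], "high")
})
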