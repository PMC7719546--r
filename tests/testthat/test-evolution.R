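test_that("Gaussian stabilizing fitness matches its closed form", {
  expect_equal(fitness(1000, 1000), 1)
  expect_equal(fitness(2000, 1000, 5e-5), exp(-50))
  expect_equal(fitness(0, 1000, 5e-5), exp(-50))
  expect_true(all(diff(fitness(seq(1000, 3000, by = 100), 1000)) < 0))
  # inverting the fitness formula gives the founder phenotype band
  dev_at <- function(w, omega = 5e-5) sqrt(log(1 / w) / omega)
  expect_equal(dev_at(0.25), 166.5, tolerance = 1e-3)
  expect_equal(dev_at(0.15), 194.8, tolerance = 1e-3)
  w <- fitness(1000 + c(166, 195), 1000)
  expect_gt(w[1], 0.25)   # just inside the deviation band -> outside window
  expect_lt(w[2], 0.15)
})

test_that("environment assignment matches the three environment models", {
  expect_equal(assign_environments(5, "constant_low"), rep(1000, 5))
  expect_equal(assign_environments(5, "constant_high"), rep(3000, 5))
  set.seed(21)
  Pe <- assign_environments(1e4, "spatial_heterogeneity")
  expect_true(all(Pe %in% c(1000, 3000)))
  frac_high <- mean(Pe == 3000)
  expect_lt(abs(frac_high - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("Wright-Fisher reproduction conserves N and follows fitness", {
  pop <- c(rep(list(tag_genotype(1)), 3), rep(list(tag_genotype(2)), 7))
  no_mut <- mutation_rates(0, 0, 0, 0, 0, 0)
  set.seed(33)
  off <- next_generation(pop, rep(1, 10), no_mut)
  expect_length(off, 10L)

  # a sole fit parent leaves the entire next generation
  w <- c(1, rep(0, 9))
  off <- next_generation(pop, w, no_mut)
  expect_true(all(vapply(off, genotype_key, character(1)) ==
                    genotype_key(pop[[1]])))

  expect_error(next_generation(pop, rep(0, 10), no_mut), "extinct")

  # free recombination: size conserved, lineages drawn from the two parents
  g9 <- random_genotype("no_signal", seed = 44)
  set.seed(45)
  offr <- next_generation(c(rep(list(g9), 5), rep(list(tag_genotype(9)), 5)),
                          rep(1, 10), no_mut, recombination = TRUE)
  expect_length(offr, 10L)
  all_lineages <- unique(c(vapply(unclass(g9), `[[`, integer(1), "lineage_id"), 9L))
  for (o in offr) {
    lo <- vapply(unclass(o), `[[`, integer(1), "lineage_id")
    expect_true(all(lo %in% all_lineages))
  }
  # identical parents recombine to the same gene content (order may differ;
  # gene order carries identity but not regulation)
  set.seed(46)
  offs <- next_generation(rep(list(g9), 4), rep(1, 4), no_mut,
                          recombination = TRUE)
  parent_genes <- sort(vapply(unclass(g9), devonet:::gene_key, character(1)))
  for (o in offs) {
    expect_identical(sort(vapply(unclass(o), devonet:::gene_key,
                                 character(1))), parent_genes)
  }

  # neutrality: expected frequency is conserved over one generation
  set.seed(34)
  k1 <- genotype_key(pop[[1]])
  freqs <- replicate(400, {
    off <- next_generation(pop, rep(1, 10), no_mut)
    mean(vapply(off, genotype_key, character(1)) == k1)
  })
  expect_lt(abs(mean(freqs) - 0.3), 3 * sd(freqs) / sqrt(length(freqs)))
})

test_that("founder rejection sampling lands in the fitness window", {
  cfg <- evolution_config(N = 30, generations = 0, environment = "constant_low",
                          treatment = "no_signal", n_found = 400,
                          assay = assay_config(n_redevelop = 100))
  f <- found_population(cfg, seed = 91)
  expect_gt(f$mean_fitness, 0.15)
  expect_lt(f$mean_fitness, 0.25)
  expect_length(f$population, 30L)
  keys <- vapply(f$population, genotype_key, character(1))
  expect_length(unique(keys), 1L)

  # the assayed mean phenotype sits in the band obtained by inverting the
  # Gaussian fitness, corrected for developmental noise (Jensen gap):
  # for P ~ N(mu, s^2), E[w] = exp(-omega d^2 / (1 + 2 omega s^2)) /
  # sqrt(1 + 2 omega s^2) with d = |mu - Pe|.
  sig <- signal_spec("none", 1000)
  set.seed(14)
  ph <- develop_many(f$founder, 400, sig)
  s2 <- var(ph)
  shrink <- 1 + 2 * cfg$omega * s2
  d_of_w <- function(w) sqrt(log(1 / (w * sqrt(shrink))) * shrink / cfg$omega)
  d_lo <- d_of_w(0.25)   # closer bound
  d_hi <- d_of_w(0.15)
  d_obs <- abs(mean(ph) - 1000)
  # allow for the finite-sample SE of both assays
  se <- 3 * sd(ph) / sqrt(length(ph))
  expect_gt(d_obs, d_lo - se - 10)
  expect_lt(d_obs, d_hi + se + 10)
})

test_that("simulations are reproducible and record the founder at generation zero", {
  cfg <- evolution_config(N = 20, generations = 4, environment = "constant_low",
                          treatment = "no_signal", n_found = 150,
                          sampling_schedule = c(0L, 2L),
                          assay = assay_config(n_redevelop = 50))
  r1 <- run_simulation(cfg, seed = 5)
  r2 <- run_simulation(cfg, seed = 5)
  expect_identical(genotype_key(r1$final_genotype),
                   genotype_key(r2$final_genotype))
  expect_identical(r1$samples, r2$samples)
  expect_equal(r1$samples$generation, c(0L, 2L, 4L))
  expect_identical(r1$samples$genotype_key[1], genotype_key(r1$founder))
  expect_true(all(r1$samples$frequency > 0 & r1$samples$frequency <= 1))

  cfg0 <- evolution_config(N = 20, generations = 0,
                           environment = "constant_low",
                           treatment = "no_signal", n_found = 150,
                           assay = assay_config(n_redevelop = 50))
  r0 <- run_simulation(cfg0, seed = 6)
  expect_equal(nrow(r0$samples), 1L)
  expect_equal(r0$samples$generation, 0L)
  expect_identical(genotype_key(r0$final_genotype), genotype_key(r0$founder))
})

test_that("populations adapt toward the optimum under constant stabilizing selection", {
  # founders are forced off the optimum (fitness window 0.15-0.25); with
  # selection on realized phenotypes the final common genotype should
  # develop closer to the optimum than the founder in most replicates
  n_rep <- 8L
  dev_founder <- dev_final <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    cfg <- evolution_config(N = 100, generations = 600,
                            environment = "constant_low",
                            treatment = "no_signal",
                            assay = assay_config(n_redevelop = 500))
    rec <- run_simulation(cfg, seed = devonet:::derive_seed(700, k))
    dev_founder[k] <- abs(rec$founder_assay$mean_low - 1000)
    dev_final[k] <- abs(rec$final_assay$mean_low - 1000)
  }
  # directional check: deviations from the optimum shrink.  At this scale
  # the mutation supply (~15 events per run) makes improvements rare and
  # occasionally large, so the claim is about direction, not magnitude: a
  # majority of replicates move toward the optimum and the mean deviation
  # falls
  expect_gte(mean(dev_founder > dev_final), 0.5)
  expect_gt(mean(dev_founder - dev_final), 0)
})
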