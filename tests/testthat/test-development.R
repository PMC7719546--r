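test_that("Hill effective signal matches its closed form", {
  K <- 2e4
  expect_equal(effective_signal(K, 3.7, K), 0.5)
  expect_equal(effective_signal(K, 1, K), 0.5)
  expect_equal(effective_signal(0, 2, K), 0)
  expect_equal(effective_signal(3 * K, 1, K), 0.75)
  # monotone increasing in S for a range of Hill coefficients
  for (n in c(1, 2.5, 5)) {
    S <- seq(0, 1e5, length.out = 50)
    expect_true(all(diff(effective_signal(S, n, K)) > 0))
  }
  expect_error(effective_signal(10, 0.5, K))
})

test_that("signal input rates follow the signalling mode", {
  expect_equal(signal_input_rate(signal_spec("environmental", 3000), Pt = 0), 3000)
  expect_equal(signal_input_rate(signal_spec("environmental", 3000), Pt = 5000), 3000)
  expect_equal(signal_input_rate(signal_spec("performance", 1000), Pt = 1000), 0)
  expect_equal(signal_input_rate(signal_spec("performance", 1000), Pt = 250), 750)
  expect_equal(signal_input_rate(signal_spec("performance", 1000), Pt = 1600), 600)
  expect_equal(signal_input_rate(signal_spec("none", 1000), Pt = 500), 0)
})

test_that("site occupancy saturates and mismatches weaken binding", {
  p <- regulation_params()
  expect_equal(site_occupancy(0, 0, p), 0)
  expect_equal(site_occupancy(p$K0, 0, p), 0.5)
  X <- 150
  occ <- site_occupancy(X, 0:10, p)
  expect_true(all(diff(occ) < 0))
  expect_lt(site_occupancy(X, 10, p), 1e-2)
  expect_true(all(diff(site_occupancy(seq(0, 1e4, by = 100), 2, p)) > 0))
})

test_that("transcription rate integrates activators and repressors as specified", {
  p <- regulation_params()
  # no regulator matches any site -> silent gene
  silent <- genotype(list(gene("regulatory", rep(5L, 20), rep(1, 20),
                               rep(0L, 20), 1, 19L, lineage_id = 1L)))
  st <- cell_state(silent, protein = 500, basic_tf = 500)
  expect_equal(transcription_rate(silent[[1]], st, silent, p), 0)

  # saturation: huge activation approaches r_max
  sat <- saturated_genotype()
  st <- cell_state(sat, protein = 0, basic_tf = 200)
  expect_equal(transcription_rate(sat[[1]], st, sat, p), p$r_max,
               tolerance = 1e-6)

  # adding repression strictly decreases the rate
  act_rep <- genotype(list(
    gene("regulatory", c(0L, 1L, rep(2L, 18)), c(2, 1, rep(0, 18)),
         rep(0L, 20), 1, 19L, lineage_id = 1L),
    gene("regulatory", rep(2L, 20), rep(0, 20), rep(0L, 20),
         -1, 1L, lineage_id = 2L)   # repressor protein targeting motif 1
  ))
  st_lo <- cell_state(act_rep, protein = c(0, 100), basic_tf = 200)
  st_hi <- cell_state(act_rep, protein = c(0, 300), basic_tf = 200)
  r_lo <- transcription_rate(act_rep[[1]], st_lo, act_rep, p)
  r_hi <- transcription_rate(act_rep[[1]], st_hi, act_rep, p)
  expect_gt(r_lo, 0)
  expect_lt(r_hi, r_lo)

  # closed-form check of the A/(1+A+R) composition for one configuration
  theta_a <- 200 / (200 + p$K0)
  theta_r <- 100 / (100 + p$K0)
  A <- 2 * theta_a
  R <- 1 * theta_r
  expect_equal(r_lo, p$r_max * A / (1 + A + R))
})

test_that("compiled transcription rates agree with the R reference", {
  p <- regulation_params()
  set.seed(99)
  for (tr in c("no_signal", "environmental_signal", "performance_signal")) {
    for (rep in 1:5) {
      g <- random_genotype(tr)
      st <- random_state(g)
      r_ref <- vapply(seq_along(g), function(j)
        transcription_rate(g[[j]], st, g, p), numeric(1))
      r_cpp <- devonet:::cpp_transcription_rates(
        devonet:::compile_genotype(g), st$protein, st$basic_tf, st$signal, p)
      expect_equal(r_cpp, r_ref, tolerance = 1e-12)
    }
  }
})

test_that("development is seeded-deterministic and ignores Pe without a signal", {
  g <- random_genotype("no_signal", seed = 12)
  a <- develop(g, signal_spec("none", 1000), seed = 101, record_every = 20)
  b <- develop(g, signal_spec("none", 3000), seed = 101, record_every = 20)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_phenotype, b$final_phenotype)

  c1 <- develop(g, signal_spec("none", 1000), seed = 101)
  expect_identical(c1$final_phenotype, a$final_phenotype)
})

test_that("phenotype trajectories are monotone and counts non-negative integers", {
  set.seed(31)
  for (tr in c("no_signal", "performance_signal")) {
    g <- random_genotype(tr)
    mode <- treatment_mode(tr)
    res <- develop(g, signal_spec(mode, 1000), record_every = 5)
    tr_df <- res$trajectory
    expect_true(all(diff(tr_df$phenotype) >= 0))
    counts <- as.matrix(tr_df[, grep("^(mrna|protein|basic_tf|signal)",
                                     names(tr_df))])
    expect_true(all(counts >= 0))
    expect_true(all(counts == round(counts)))
  }
})

test_that("a genotype without phenotype genes develops a zero phenotype", {
  g <- genotype(list(gene("regulatory", rep(0L, 20), rep(1, 20), rep(0L, 20),
                          1, 0L, lineage_id = 1L)))
  expect_equal(develop(g, seed = 3)$final_phenotype, 0)
  expect_equal(develop(genotype(), seed = 3)$final_phenotype, 0)
})

test_that("constitutive expression matches the analytic birth-death stationary mean", {
  p <- regulation_params()
  g <- saturated_genotype()
  set.seed(71)
  res <- develop_many(g, 1000, signal_spec("none", 1000), p,
                      final_counts = TRUE)
  # mRNA ~ birth-death(r_max, mrna_decay); protein mean = mRNA mean *
  # translation_rate / protein_decay
  m_expect <- p$r_max / p$mrna_decay
  p_expect <- m_expect * p$translation_rate / p$protein_decay
  m_obs <- res$mrna[1, ]
  p_obs <- res$protein[1, ]
  expect_lt(abs(mean(m_obs) - m_expect), 3 * sd(m_obs) / sqrt(length(m_obs)))
  expect_lt(abs(mean(p_obs) - p_expect), 3 * sd(p_obs) / sqrt(length(p_obs)))
})

test_that("halving tau does not shift the stationary mean", {
  g <- saturated_genotype()
  set.seed(72)
  m1 <- develop_many(g, 600, params = regulation_params(tau = 0.5),
                     final_counts = TRUE)$mrna[1, ]
  m2 <- develop_many(g, 600, params = regulation_params(tau = 0.25),
                     final_counts = TRUE)$mrna[1, ]
  se <- sqrt(sd(m1)^2 / length(m1) + sd(m2)^2 / length(m2))
  expect_lt(abs(mean(m1) - mean(m2)), 2.5 * se)
})
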