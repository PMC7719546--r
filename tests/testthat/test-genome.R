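test_that("random founder genotypes have the right composition and are reproducible", {
  g <- random_genotype("no_signal", seed = 1)
  expect_s3_class(g, "genotype")
  expect_length(g, 6L)
  expect_equal(unname(gene_counts(g)), c(3L, 3L, 0L))

  for (tr in c("environmental_signal", "performance_signal")) {
    gs <- random_genotype(tr, seed = 2)
    expect_length(gs, 9L)
    expect_equal(gene_counts(gs)[["signal_binding"]], 3L)
    hn <- vapply(unclass(gs)[gene_kinds(gs) == "signal_binding"],
                 `[[`, numeric(1), "hill_n")
    expect_true(all(hn >= 1 & hn <= 5))
    pe <- vapply(unclass(gs)[gene_kinds(gs) == "phenotype"],
                 `[[`, numeric(1), "phenotype_effect")
    expect_true(all(pe > 0))
  }

  expect_identical(genotype_key(random_genotype("no_signal", seed = 7)),
                   genotype_key(random_genotype("no_signal", seed = 7)))
  expect_error(random_genotype("nonsense"))
})

test_that("gene constructor enforces field invariants", {
  ok <- function(...) gene(site_motif = rep(0L, 20), site_effect = rep(0, 20),
                           site_mismatch = rep(0L, 20), inherent_effect = 1,
                           target_motif = 0L, lineage_id = 1L, ...)
  expect_error(ok(kind = "phenotype"))                       # needs effect
  expect_error(ok(kind = "regulatory", phenotype_effect = 1))
  expect_error(ok(kind = "signal_binding", hill_n = 7))
  expect_error(ok(kind = "regulatory", hill_n = 2))
  expect_silent(ok(kind = "phenotype", phenotype_effect = 0.5))
  expect_error(gene("regulatory", rep(25L, 20), rep(0, 20), rep(0L, 20),
                    1, 0L, lineage_id = 1L))                 # motif range
})

test_that("mutation is the identity at zero rates and preserves gene kinds", {
  g <- random_genotype("performance_signal", seed = 3)
  zero <- mutation_rates(0, 0, 0, 0, 0, 0)
  set.seed(1)
  expect_identical(genotype_key(mutate_genome(g, zero)), genotype_key(g))

  # force many events through every channel; kinds only change in count
  hot <- mutation_rates(duplication = 0.5, deletion = 0.05,
                        inherent_effect = 0.5, binding_affinity = 0.5,
                        target_motif = 0.5, cis_effect = 0.5)
  set.seed(42)
  m <- g
  for (i in 1:50) m <- mutate_genome(m, hot)
  expect_true(all(gene_kinds(m) %in% c("regulatory", "phenotype",
                                       "signal_binding")))
  expect_true(all(vapply(unclass(m), function(x) {
    validate_gene_ok <- tryCatch({ devonet:::validate_gene(x); TRUE },
                                 error = function(e) FALSE)
    validate_gene_ok
  }, logical(1))))
  # mismatches stayed inside the reflecting bounds
  mm <- unlist(lapply(unclass(m), `[[`, "site_mismatch"))
  expect_true(all(mm >= 0 & mm <= 10))
})

test_that("duplication appends an exact copy and deletion can empty a kind", {
  g <- random_genotype("no_signal", seed = 4)
  dup_only <- mutation_rates(duplication = 3, deletion = 0, 0, 0, 0, 0)
  set.seed(5)
  d <- mutate_genome(g, dup_only)
  ev <- attr(d, "mutation_events")
  expect_gt(ev[["duplication"]], 0)
  expect_length(d, length(g) + ev[["duplication"]])
  # appended copies are byte-identical to a gene of the parent, lineage too
  extra <- unclass(d)[(length(g) + 1):length(d)]
  parent_keys <- vapply(unclass(g), devonet:::gene_key, character(1))
  expect_true(all(vapply(extra, devonet:::gene_key, character(1)) %in%
                    parent_keys))

  # deleting everything leaves a valid, developable empty genotype
  one <- genotype(list(gene("phenotype", rep(0L, 20), rep(0, 20), rep(0L, 20),
                            1, 0L, phenotype_effect = 1, lineage_id = 1L)))
  del_all <- mutation_rates(duplication = 0, deletion = 1, 0, 0, 0, 0)
  set.seed(6)
  e <- mutate_genome(one, del_all)
  expect_length(e, 0L)
  expect_equal(develop(e, seed = 1)$final_phenotype, 0)
})

test_that("realized mutation event frequencies recover the configured rates", {
  # single-gene genome so per-gene and per-genome rates coincide
  g <- tag_genotype(1)
  rate <- 2e-4
  rts <- mutation_rates(duplication = rate, deletion = rate,
                        inherent_effect = rate, binding_affinity = rate,
                        target_motif = rate, cis_effect = rate)
  n_rep <- 1e6L
  set.seed(11)
  tot <- c(duplication = 0L, deletion = 0L, inherent_effect = 0L,
           binding_affinity = 0L, target_motif = 0L, cis_effect = 0L)
  for (i in seq_len(n_rep)) {
    tot <- tot + attr(mutate_genome(g, rts), "mutation_events")
  }
  # 99% binomial acceptance band around the configured rate
  lo <- qbinom(0.005, n_rep, rate)
  hi <- qbinom(0.995, n_rep, rate)
  for (ch in names(tot)) {
    expect_gte(tot[[ch]], lo)
    expect_lte(tot[[ch]], hi)
  }
})

test_that("canonical keys separate genotypes and serialization round-trips", {
  g <- random_genotype("environmental_signal", seed = 8)
  g2 <- unserialize(serialize(g, NULL))     # deep copy
  expect_identical(genotype_key(g), genotype_key(g2))

  tweaked <- unclass(g2)
  tweaked[[1]]$site_effect[5] <- tweaked[[1]]$site_effect[5] + 1e-12
  expect_false(genotype_key(structure(tweaked, class = "genotype")) ==
                 genotype_key(g))

  swapped <- g[c(2L, 1L, 3:length(g))]
  expect_false(genotype_key(swapped) == genotype_key(g))

  # JSON round trip is the identity (keys equal => every field equal)
  for (seed in 1:5) {
    h <- random_genotype("performance_signal", seed = seed)
    expect_identical(genotype_key(genotype_from_json(genotype_json(h))),
                     genotype_key(h))
  }
  # and survives a file round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_genotype(g, path)
  expect_identical(genotype_key(read_genotype(path)), genotype_key(g))
})
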