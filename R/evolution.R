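# Wright-Fisher evolutionary loop: nonoverlapping generations, constant
# population size, haploid clonal reproduction with fitness-proportional
# parentage, Gaussian stabilizing selection on the phenotype at the end of
# development.

#' Gaussian stabilizing-selection fitness
#'
#' `w = exp(-omega * (P - Pe)^2)`: 1 exactly at the optimum, strictly
#' decreasing in the deviation.
#'
#' @param P Realized phenotype(s).
#' @param Pe Environmental optimum.
#' @param omega Selection strength (phenotype-units^-2).
#' @return Fitness in `(0, 1]`.
#' @export
fitness <- function(P, Pe, omega = 5e-5) {
  stopifnot(omega > 0)
  exp(-omega * (P - Pe)^2)
}

#' Configuration of one evolutionary simulation
#'
#' @param N Population size.
#' @param generations Number of generations to simulate.
#' @param omega Strength of stabilizing selection.
#' @param environment `"constant_low"`, `"constant_high"` or
#'   `"spatial_heterogeneity"` (each individual assigned independently to
#'   either environment with probability 1/2 every generation, i.e. a
#'   migration rate of 0.5).
#' @param treatment Signal treatment (`"no_signal"`,
#'   `"environmental_signal"`, `"performance_signal"`).
#' @param Pe_low,Pe_high Optimal phenotypes of the two environments.
#' @param sampling_schedule Generations at which the most common genotype
#'   is recorded (the final generation is always recorded).
#' @param rates A [mutation_rates()].
#' @param params A [regulation_params()].
#' @param priors A [founder_priors()].
#' @param n_found Developments per candidate in the founder fitness assay.
#' @param founder_window Open interval the founder's assayed mean fitness
#'   must fall in.
#' @param founder_max_tries Cap on rejection-sampling attempts.
#' @param assay An [assay_config()] applied to the founder and the final
#'   most common genotype.
#' @return A validated configuration list.
#' @export
evolution_config <- function(N = 10000, generations = 100000, omega = 5e-5,
                             environment = c("constant_low", "constant_high",
                                             "spatial_heterogeneity"),
                             treatment = c("no_signal", "environmental_signal",
                                           "performance_signal"),
                             Pe_low = 1000, Pe_high = 3000,
                             sampling_schedule = integer(0),
                             rates = mutation_rates(),
                             params = regulation_params(),
                             priors = founder_priors(),
                             n_found = 1000, founder_window = c(0.15, 0.25),
                             founder_max_tries = 1e5,
                             assay = assay_config(n_redevelop = 2000)) {
  environment <- match.arg(environment)
  treatment <- match.arg(treatment)
  stopifnot(N >= 2, generations >= 0, omega > 0, Pe_low > 0, Pe_high > 0,
            n_found >= 1, founder_max_tries >= 1,
            length(founder_window) == 2L,
            founder_window[1] > 0, founder_window[2] <= 1,
            founder_window[1] < founder_window[2])
  list(N = as.integer(N), generations = as.integer(generations),
       omega = omega, environment = environment, treatment = treatment,
       Pe_low = Pe_low, Pe_high = Pe_high,
       sampling_schedule = as.integer(sampling_schedule),
       rates = rates, params = params, priors = priors,
       n_found = as.integer(n_found), founder_window = founder_window,
       founder_max_tries = as.integer(founder_max_tries),
       assay = assay)
}

#' Assign individuals to environments
#'
#' Constant models put every individual at the same optimum; spatial
#' heterogeneity assigns each individual independently to either optimum
#' with probability 1/2 each generation.
#'
#' @param N Number of individuals.
#' @param environment Environment model name (see [evolution_config()]).
#' @param Pe_low,Pe_high The two optima.
#' @return Numeric vector of per-individual optima.
#' @export
assign_environments <- function(N, environment = c("constant_low",
                                                   "constant_high",
                                                   "spatial_heterogeneity"),
                                Pe_low = 1000, Pe_high = 3000) {
  environment <- match.arg(environment)
  switch(environment,
         constant_low = rep(Pe_low, N),
         constant_high = rep(Pe_high, N),
         spatial_heterogeneity = ifelse(runif(N) < 0.5, Pe_low, Pe_high))
}

#' One Wright-Fisher generation
#'
#' Draws `N` offspring by fitness-proportional multinomial sampling of
#' parents and passes each offspring genome through [mutate_genome()] once
#' (one replication).  Reproduction is clonal by default; with
#' `recombination = TRUE` each offspring draws two parents and inherits
#' each gene lineage (all genes sharing a lineage id) from one of them by
#' an independent fair coin flip (free recombination between lineages).
#' With variable gene numbers there is no canonical recombination map;
#' the clonal default is what the package's results are built on.
#'
#' @param pop List of `N` genotypes.
#' @param fitnesses Non-negative per-individual fitnesses, not all zero.
#' @param rates A [mutation_rates()].
#' @param recombination Use two-parent free recombination between gene
#'   lineages instead of clonal reproduction.
#' @return The offspring population (list of `N` genotypes).
#' @export
next_generation <- function(pop, fitnesses, rates = mutation_rates(),
                            recombination = FALSE) {
  N <- length(pop)
  stopifnot(length(fitnesses) == N, all(fitnesses >= 0))
  if (all(fitnesses == 0))
    stop("population extinct: all fitnesses are zero")
  if (!recombination) {
    parents <- sample.int(N, N, replace = TRUE, prob = fitnesses)
    return(lapply(parents, function(i)
      with_compiled(mutate_genome(pop[[i]], rates))))
  }
  p1 <- sample.int(N, N, replace = TRUE, prob = fitnesses)
  p2 <- sample.int(N, N, replace = TRUE, prob = fitnesses)
  lapply(seq_len(N), function(k) {
    with_compiled(mutate_genome(recombine(pop[[p1[k]]], pop[[p2[k]]]), rates))
  })
}

# Free recombination between gene lineages: every lineage id present in
# either parent is inherited from one parent chosen by a fair coin flip
# (lineages private to one parent may therefore be lost).  Gene order
# within each parent is preserved, first parent's genes first.
recombine <- function(a, b) {
  la <- vapply(unclass(a), `[[`, integer(1), "lineage_id")
  lb <- vapply(unclass(b), `[[`, integer(1), "lineage_id")
  lineages <- union(la, lb)
  from_a <- lineages[runif(length(lineages)) < 0.5]
  genotype(c(unclass(a)[la %in% from_a], unclass(b)[!(lb %in% from_a)]))
}

#' Found a population by rejection sampling
#'
#' Draws random genotypes until one has an assayed mean fitness inside
#' `founder_window` and clones it `N` times.  The assay develops the
#' candidate `n_found` times in the low environment under the treatment's
#' signal mode and averages the per-development fitnesses.  A cheap
#' pre-screen with a few developments discards candidates whose rough mean
#' fitness is far outside the window before the full assay is spent.
#'
#' @param config An [evolution_config()].
#' @param seed Optional integer seed.
#' @return A list with `founder` (the genotype), `population` (`N` clones),
#'   `mean_fitness`, `mean_phenotype` and `tries`.
#' @export
found_population <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sig <- signal_spec(treatment_mode(config$treatment), Pe = config$Pe_low)
  n_screen <- min(25L, config$n_found)
  for (try in seq_len(config$founder_max_tries)) {
    cand <- random_genotype(config$treatment, config$priors)
    ph <- develop_many(cand, n_screen, sig, config$params)
    w_rough <- mean(fitness(ph, config$Pe_low, config$omega))
    if (w_rough < 0.04 || w_rough > 0.6) next
    if (config$n_found > n_screen) {
      ph <- c(ph, develop_many(cand, config$n_found - n_screen, sig,
                               config$params))
    }
    w <- mean(fitness(ph, config$Pe_low, config$omega))
    if (w > config$founder_window[1] && w < config$founder_window[2]) {
      cand <- with_compiled(cand)
      return(list(founder = cand,
                  population = rep(list(cand), config$N),
                  mean_fitness = w, mean_phenotype = mean(ph), tries = try))
    }
  }
  stop(sprintf("no founder with mean fitness in (%g, %g) found in %d tries",
               config$founder_window[1], config$founder_window[2],
               config$founder_max_tries))
}

most_common <- function(pop) {
  keys <- vapply(pop, genotype_key, character(1))
  tab <- table(keys)
  top_key <- names(tab)[which.max(tab)]   # ties: first in key order
  idx <- match(top_key, keys)             # first occurrence in population
  list(genotype = pop[[idx]], key = top_key,
       frequency = as.integer(tab[top_key]) / length(pop))
}

#' Run one evolutionary simulation
#'
#' Founds a population, then iterates environment assignment, development
#' of every individual (one stochastic development each; selection acts on
#' realized phenotypes), fitness evaluation, and Wright-Fisher reproduction
#' with mutation.  The most common genotype is recorded at the scheduled
#' generations and at the final generation, and both the founder and the
#' final most common genotype are assayed for plasticity and developmental
#' noise.  Deterministic given `(config, seed)`.
#'
#' @param config An [evolution_config()].
#' @param seed Integer master seed; independent child streams are derived
#'   for founding, environments/development/reproduction, and assays.
#' @return An object of class `"simulation_record"`.
#' @export
run_simulation <- function(config, seed = 1L) {
  founded <- found_population(config, seed = derive_seed(seed, "found"))
  pop <- founded$population
  set.seed(derive_seed(seed, "generations"))
  sig_mode <- treatment_mode(config$treatment)

  samples <- list()
  record_sample <- function(generation, pop, mean_fitness, mean_phenotype) {
    mc <- most_common(pop)
    samples[[length(samples) + 1L]] <<- data.frame(
      generation = generation, frequency = mc$frequency,
      mean_fitness = mean_fitness, mean_phenotype = mean_phenotype,
      genotype_key = mc$key, genotype_json = genotype_json(mc$genotype),
      stringsAsFactors = FALSE)
    mc$genotype
  }

  sched <- unique(sort(config$sampling_schedule))
  sched <- sched[sched >= 0 & sched < config$generations]
  final_genotype <- founded$founder
  if (0L %in% sched || config$generations == 0L) {
    final_genotype <- record_sample(0L, pop, founded$mean_fitness,
                                    founded$mean_phenotype)
  }

  for (gen in seq_len(config$generations)) {
    Pe <- assign_environments(config$N, config$environment,
                              config$Pe_low, config$Pe_high)
    P <- cpp_develop_population(lapply(pop, attr, "compiled"),
                                signal_mode_code(sig_mode), Pe,
                                config$params)
    w <- fitness(P, Pe, config$omega)
    pop <- next_generation(pop, w, config$rates)
    if (gen %in% sched || gen == config$generations) {
      # logged fitness/phenotype are the parental generation's realized values
      final_genotype <- record_sample(gen, pop, mean(w), mean(P))
    }
  }

  assay_seed <- derive_seed(seed, "assay")
  founder_assay <- assay_genotype(founded$founder, config$treatment,
                                  config$assay, config$params,
                                  seed = derive_seed(assay_seed, "founder"),
                                  Pe_low = config$Pe_low,
                                  Pe_high = config$Pe_high)
  final_assay <- assay_genotype(final_genotype, config$treatment,
                                config$assay, config$params,
                                seed = derive_seed(assay_seed, "final"),
                                Pe_low = config$Pe_low,
                                Pe_high = config$Pe_high)

  structure(list(
    config = config, seed = as.integer(seed),
    founder = founded$founder,
    founder_mean_fitness = founded$mean_fitness,
    founder_assay = founder_assay,
    final_genotype = final_genotype,
    final_assay = final_assay,
    samples = do.call(rbind, samples),
    gene_counts = gene_counts(final_genotype)
  ), class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  cat(sprintf(
    "<simulation_record: %s / %s, N = %d, %d generations>\n",
    x$config$treatment, x$config$environment, x$config$N,
    x$config$generations))
  cat(sprintf("  founder:  mean fitness %.3f, plastic = %s\n",
              x$founder_mean_fitness, x$founder_assay$is_plastic))
  cat(sprintf(
    "  final:    mean_low %.1f, mean_high %.1f, noise %.1f, plastic = %s\n",
    x$final_assay$mean_low, x$final_assay$mean_high, x$final_assay$sd_low,
    x$final_assay$is_plastic))
  invisible(x)
}
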