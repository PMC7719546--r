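# Reaction norms, plasticity classification, developmental noise, and
# experiment-level summary statistics.

#' Assay configuration
#'
#' @param n_redevelop Replicate redevelopments per environment (50,000 in
#'   full-scale work; tests use far fewer).
#' @param delta_P Plasticity threshold: a genotype is plastic when its
#'   reaction-norm difference strictly exceeds `delta_P` (default 400,
#'   i.e. 20% of the difference between the optima; 100, 200 and 800 are
#'   reasonable alternatives).
#' @return A validated list.
#' @export
assay_config <- function(n_redevelop = 50000, delta_P = 400) {
  stopifnot(n_redevelop >= 2, delta_P > 0)
  list(n_redevelop = as.integer(n_redevelop), delta_P = delta_P)
}

#' Reaction norm of a genotype
#'
#' Mean final phenotype over `n_redevelop` independent redevelopments in
#' each environment, under the treatment's signal mode in both.
#'
#' @param g A [genotype()].
#' @param treatment Signal treatment name.
#' @param assay An [assay_config()].
#' @param params A [regulation_params()].
#' @param seed Optional integer seed.
#' @param Pe_low,Pe_high The two environmental optima.
#' @return Named numeric vector `c(mean_low, mean_high)`.
#' @export
reaction_norm <- function(g, treatment = "no_signal",
                          assay = assay_config(), params = regulation_params(),
                          seed = NULL, Pe_low = 1000, Pe_high = 3000) {
  mode <- treatment_mode(treatment)
  # paired streams: with a seed, both environments replay the same
  # randomness, so the reaction norm of a signal-blind genotype is exactly
  # flat and the difference estimate has reduced sampling variance
  lo <- develop_many(g, assay$n_redevelop, signal_spec(mode, Pe_low), params,
                     seed = seed)
  hi <- develop_many(g, assay$n_redevelop, signal_spec(mode, Pe_high), params,
                     seed = seed)
  c(mean_low = mean(lo), mean_high = mean(hi))
}

#' Classify a reaction norm as plastic
#'
#' Strict threshold on the absolute reaction-norm difference:
#' `|mean_high - mean_low| > delta_P`.  Symmetric in its two means.
#'
#' @param mean_low,mean_high Mean phenotypes in the two environments.
#' @param delta_P Threshold (default 400).
#' @return Logical flag.
#' @export
classify_plastic <- function(mean_low, mean_high, delta_P = 400) {
  stopifnot(delta_P > 0)
  abs(mean_high - mean_low) > delta_P
}

#' Developmental noise of a genotype
#'
#' Sample standard deviation (n - 1 denominator) of final phenotypes over
#' replicate redevelopments in the low environment; developmental
#' robustness is its inverse.
#'
#' @inheritParams reaction_norm
#' @return The standard deviation.
#' @export
developmental_noise <- function(g, treatment = "no_signal",
                                assay = assay_config(),
                                params = regulation_params(), seed = NULL,
                                Pe_low = 1000) {
  if (!is.null(seed)) set.seed(seed)
  mode <- treatment_mode(treatment)
  sd(develop_many(g, assay$n_redevelop, signal_spec(mode, Pe_low), params))
}

#' Full plasticity and noise assay of one genotype
#'
#' One set of `n_redevelop` redevelopments per environment provides the
#' reaction norm, the plasticity call, and (from the low-environment set)
#' the developmental noise.
#'
#' @inheritParams reaction_norm
#' @return An object of class `"assay_result"`: a list with `mean_low`,
#'   `mean_high`, `sd_low`, `is_plastic`, `n_redevelop`.
#' @export
assay_genotype <- function(g, treatment = "no_signal",
                           assay = assay_config(),
                           params = regulation_params(), seed = NULL,
                           Pe_low = 1000, Pe_high = 3000) {
  mode <- treatment_mode(treatment)
  lo <- develop_many(g, assay$n_redevelop, signal_spec(mode, Pe_low), params,
                     seed = seed)
  hi <- develop_many(g, assay$n_redevelop, signal_spec(mode, Pe_high), params,
                     seed = seed)
  structure(list(mean_low = mean(lo), mean_high = mean(hi),
                 sd_low = sd(lo),
                 is_plastic = classify_plastic(mean(lo), mean(hi),
                                              assay$delta_P),
                 n_redevelop = assay$n_redevelop),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf(
    "<assay: mean_low %.1f, mean_high %.1f, sd_low %.2f, plastic = %s (n = %d)>\n",
    x$mean_low, x$mean_high, x$sd_low, x$is_plastic, x$n_redevelop))
  invisible(x)
}

se_mean <- function(x) if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_

# Welch t-test that tolerates degenerate (constant) samples: identical
# constant groups give t = 0, p = 1; distinct constant groups t = Inf/-Inf,
# p = 0.
welch_safe <- function(x, y) {
  tryCatch(t.test(x, y), error = function(e) {
    d <- mean(x) - mean(y)
    list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
         p.value = if (d == 0) 1 else 0)
  })
}

#' Summarize a set of simulation records
#'
#' Groups records by treatment-by-environment cell and reports, per cell:
#' the number of replicates, how many founders were plastic, the fraction
#' of final genotypes plastic among all replicates and among those whose
#' founder was not plastic (both are reported because founders can start
#' plastic), and mean +/- SE of developmental noise split by final
#' plasticity.  Pairwise Welch t-tests compare noise between cells
#' (plastic and nonplastic final genotypes separately) and pairwise Fisher
#' exact tests compare the fractions evolving plasticity among
#' initially-nonplastic replicates.  Empty quantities are reported as `NA`
#' with the counts that explain them, never silently dropped.
#'
#' @param records List of `simulation_record` objects (see
#'   [run_simulation()]).
#' @return A list of data frames: `summary`, `noise_tests`,
#'   `plasticity_tests`.
#' @export
summarize_experiment <- function(records) {
  stopifnot(length(records) >= 1)
  cells <- vapply(records, function(r)
    paste(r$config$treatment, r$config$environment, sep = ":"), character(1))
  ucells <- unique(cells)

  per_cell <- lapply(ucells, function(cl) {
    rs <- records[cells == cl]
    start_plastic <- vapply(rs, function(r) r$founder_assay$is_plastic, logical(1))
    end_plastic <- vapply(rs, function(r) r$final_assay$is_plastic, logical(1))
    noise <- vapply(rs, function(r) r$final_assay$sd_low, numeric(1))
    nonpl0 <- !start_plastic
    list(cell = cl, n = length(rs),
         start_plastic = start_plastic, end_plastic = end_plastic,
         noise = noise, nonpl0 = nonpl0)
  })
  names(per_cell) <- ucells

  summary <- do.call(rbind, lapply(per_cell, function(x) {
    parts <- strsplit(x$cell, ":", fixed = TRUE)[[1]]
    data.frame(
      treatment = parts[1], environment = parts[2], n = x$n,
      n_start_plastic = sum(x$start_plastic),
      frac_plastic_all = mean(x$end_plastic),
      n_start_nonplastic = sum(x$nonpl0),
      frac_plastic_excl = if (any(x$nonpl0)) mean(x$end_plastic[x$nonpl0]) else NA_real_,
      noise_plastic_mean = if (any(x$end_plastic)) mean(x$noise[x$end_plastic]) else NA_real_,
      noise_plastic_se = se_mean(x$noise[x$end_plastic]),
      noise_nonplastic_mean = if (any(!x$end_plastic)) mean(x$noise[!x$end_plastic]) else NA_real_,
      noise_nonplastic_se = se_mean(x$noise[!x$end_plastic]),
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  pairs <- if (length(ucells) >= 2) utils::combn(ucells, 2, simplify = FALSE) else list()

  noise_tests <- do.call(rbind, c(list(NULL), lapply(pairs, function(pr) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(class_plastic) {
      x <- per_cell[[pr[1]]]; y <- per_cell[[pr[2]]]
      nx <- x$noise[x$end_plastic == class_plastic]
      ny <- y$noise[y$end_plastic == class_plastic]
      ok <- length(nx) >= 2 && length(ny) >= 2
      tt <- if (ok) welch_safe(nx, ny) else NULL
      data.frame(cell_a = pr[1], cell_b = pr[2],
                 class = if (class_plastic) "plastic" else "nonplastic",
                 n_a = length(nx), n_b = length(ny),
                 delta = if (ok) mean(nx) - mean(ny) else NA_real_,
                 t = if (ok) unname(tt$statistic) else NA_real_,
                 p = if (ok) tt$p.value else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })))

  plasticity_tests <- do.call(rbind, c(list(NULL), lapply(pairs, function(pr) {
    x <- per_cell[[pr[1]]]; y <- per_cell[[pr[2]]]
    ax <- sum(x$end_plastic[x$nonpl0]); bx <- sum(x$nonpl0) - ax
    ay <- sum(y$end_plastic[y$nonpl0]); by <- sum(y$nonpl0) - ay
    ok <- sum(x$nonpl0) > 0 && sum(y$nonpl0) > 0
    ft <- if (ok) fisher.test(matrix(c(ax, bx, ay, by), nrow = 2)) else NULL
    data.frame(cell_a = pr[1], cell_b = pr[2],
               plastic_a = ax, nonplastic_a = bx,
               plastic_b = ay, nonplastic_b = by,
               p = if (ok) ft$p.value else NA_real_,
               stringsAsFactors = FALSE)
  })))

  list(summary = summary, noise_tests = noise_tests,
       plasticity_tests = plasticity_tests)
}
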