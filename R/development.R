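# Development of one individual: tau-leaping over the reaction channels
# (basic-TF input, per-gene transcription, translation, mRNA and protein
# decay, signal input and decay), with deterministic phenotype growth
# catalyzed by phenotype-gene proteins.  The inner loop lives in C++
# (src/develop.cpp); the R functions here define the regulatory algebra
# and are the reference the compiled code is tested against.

#' Effective signal under cooperative binding
#'
#' Hill saturation of the signal: `Se = S^n / (K^n + S^n)`, the fraction of
#' a signal-binding protein available as an active heterodimer.  `Se` is
#' dimensionless, increases monotonically with `S`, and equals 1/2 at
#' `S = K` for every Hill coefficient.
#'
#' @param S Signal molecule count (>= 0).
#' @param n Hill coefficient in `[1, 5]`.
#' @param K Dissociation constant (> 0).
#' @return Effective signal in `[0, 1)`.
#' @export
effective_signal <- function(S, n, K) {
  stopifnot(all(S >= 0), all(n >= 1), all(n <= 5), all(K > 0))
  # K/0 = Inf makes the S = 0 limit exact; recycles over S and n
  1 / (1 + (K / S)^n)
}

#' Signal input rate
#'
#' Molecules per minute at which the signal enters the cell: 0 without a
#' signal, the environmental optimum `Pe` for the environmental signal, and
#' the current mismatch `|Pt - Pe|` for the performance signal.
#'
#' @param spec A [signal_spec()].
#' @param Pt Current phenotype (used by the performance signal only).
#' @return A non-negative rate.
#' @export
signal_input_rate <- function(spec, Pt = 0) {
  switch(spec$mode,
         none = 0,
         environmental = spec$Pe,
         performance = abs(Pt - spec$Pe))
}

#' Occupancy of a binding site
#'
#' Fraction of time a site is bound by a transcription-factor species
#' present at `X` copies: `theta = X / (X + K0 * lambda^mismatch)`.
#' Mismatches between the protein's binding domain and the site weaken
#' binding geometrically.
#'
#' @param X Copy number of the binding species (>= 0).
#' @param mismatch Site binding-affinity mismatch (integer >= 0).
#' @param params A [regulation_params()].
#' @return Occupancy in `[0, 1)`.
#' @export
site_occupancy <- function(X, mismatch, params = regulation_params()) {
  stopifnot(all(X >= 0), all(mismatch >= 0))
  X / (X + params$K0 * params$lambda_mismatch^mismatch)
}

#' Cell state constructor
#'
#' Discrete molecule counts for each gene instance plus the basic
#' transcription factor, the signal, the elapsed time and the current
#' phenotype.  Scalars are recycled across genes.
#'
#' @param g A [genotype()].
#' @param mrna,protein Per-gene counts.
#' @param basic_tf,signal Counts of the basic TF and the signal.
#' @param phenotype Current phenotype `Pt` (non-negative; never decays).
#' @param t Elapsed time (min).
#' @return A list state.
#' @export
cell_state <- function(g, mrna = 0, protein = 0, basic_tf = 0, signal = 0,
                       phenotype = 0, t = 0) {
  n <- length(g)
  st <- list(t = t,
             mrna = rep_len(as.double(mrna), n),
             protein = rep_len(as.double(protein), n),
             basic_tf = as.double(basic_tf),
             signal = as.double(signal),
             phenotype = as.double(phenotype))
  stopifnot(all(st$mrna >= 0), all(st$protein >= 0), st$basic_tf >= 0,
            st$signal >= 0, st$phenotype >= 0)
  st
}

# Active regulator species given a state: copy number, bound motif and
# inherent effect for every gene product plus the basic TF.  Signal-binding
# proteins act only as signal heterodimers, at Se(S) times their copy
# number; both partners are required.
regulator_table <- function(g, state, params) {
  n <- length(g)
  if (n > 0L) {
    kind <- gene_kinds(g)
    X <- state$protein
    sb <- kind == "signal_binding"
    if (any(sb)) {
      hn <- vapply(unclass(g)[sb], `[[`, numeric(1), "hill_n")
      X[sb] <- effective_signal(state$signal, hn, params$K_hill) * X[sb]
    }
    motif <- vapply(unclass(g), `[[`, integer(1), "target_motif")
    eff <- vapply(unclass(g), `[[`, numeric(1), "inherent_effect")
  } else {
    X <- numeric(0); motif <- integer(0); eff <- numeric(0)
  }
  list(X = c(X, state$basic_tf),
       motif = c(motif, params$basic_tf_motif),
       effect = c(eff, 1))
}

#' Transcription rate of one gene
#'
#' Michaelis-Menten-like integration of activator and repressor action over
#' the gene's 20 binding sites.  Each site receives a signed input
#' `cis_effect * inherent_effect * occupancy` from every regulator species
#' whose target motif matches the site's motif (gene products, signal
#' heterodimers, and the basic TF).  With `A` the summed positive inputs
#' and `R` the summed magnitudes of negative inputs, the rate is
#' `r_max * A / (1 + A + R)`, and 0 when `A = 0`: a gene needs at least one
#' bound activator to be expressed.
#'
#' @param gn A [gene()] (one element of `g`).
#' @param state A [cell_state()] for `g`.
#' @param g The full [genotype()] supplying the regulator species.
#' @param params A [regulation_params()].
#' @return A transcription rate in `[0, r_max)`.
#' @export
transcription_rate <- function(gn, state, g, params = regulation_params()) {
  reg <- regulator_table(g, state, params)
  A <- 0; R <- 0
  for (b in seq_len(N_SITES)) {
    hit <- reg$motif == gn$site_motif[b]
    if (!any(hit)) next
    theta <- site_occupancy(reg$X[hit], gn$site_mismatch[b], params)
    s <- gn$site_effect[b] * reg$effect[hit] * theta
    A <- A + sum(s[s > 0])
    R <- R + sum(-s[s < 0])
  }
  if (A <= 0) return(0)
  params$r_max * A / (1 + A + R)
}

# Flatten a genotype into the matrix form consumed by the C++ core; cached
# on the object as attribute "compiled".
compile_genotype <- function(g) {
  cg <- attr(g, "compiled")
  if (!is.null(cg)) return(cg)
  n <- length(g)
  gl <- unclass(g)
  kind_code <- match(gene_kinds(g), GENE_KINDS) - 1L
  list(
    n = n,
    kind = kind_code,
    site_motif = if (n) vapply(gl, `[[`, integer(N_SITES), "site_motif") else matrix(0L, N_SITES, 0),
    site_effect = if (n) vapply(gl, `[[`, numeric(N_SITES), "site_effect") else matrix(0, N_SITES, 0),
    site_mismatch = if (n) vapply(gl, `[[`, integer(N_SITES), "site_mismatch") else matrix(0L, N_SITES, 0),
    inherent = if (n) vapply(gl, `[[`, numeric(1), "inherent_effect") else numeric(0),
    target = if (n) vapply(gl, `[[`, integer(1), "target_motif") else integer(0),
    phen_effect = if (n) {
      pe <- vapply(gl, `[[`, numeric(1), "phenotype_effect")
      ifelse(is.na(pe), 0, pe)
    } else numeric(0),
    hill_n = if (n) {
      hn <- vapply(gl, `[[`, numeric(1), "hill_n")
      ifelse(is.na(hn), 1, hn)
    } else numeric(0)
  )
}

with_compiled <- function(g) {
  if (is.null(attr(g, "compiled"))) attr(g, "compiled") <- compile_genotype(g)
  g
}

#' Develop one individual
#'
#' Simulates a single cell's development for `T_dev` minutes from an empty
#' initial state (all counts zero, phenotype zero).  Each tau-step draws
#' independent Poisson event counts for every reaction channel from the
#' state at the start of the step, clamps counts at zero, and grows the
#' phenotype deterministically by `tau * k_P * sum(protein * phenotype
#' effect)` over phenotype genes.  The phenotype never decreases.
#'
#' @param g A [genotype()].
#' @param signal A [signal_spec()]; with mode `"none"` the result is
#'   independent of `Pe`.
#' @param params A [regulation_params()].
#' @param seed Optional integer seed set before simulating.
#' @param record_every Record the state every this many steps into a
#'   trajectory data frame (0 = no trajectory).
#' @return A list with `final_phenotype`, `final_state` (a [cell_state()])
#'   and `trajectory` (a data frame or `NULL`).
#' @export
develop <- function(g, signal = signal_spec(), params = regulation_params(),
                    seed = NULL, record_every = 0) {
  if (!is.null(seed)) set.seed(seed)
  cg <- compile_genotype(g)
  res <- cpp_develop(cg, signal_mode_code(signal$mode), signal$Pe, 1L,
                     params, as.integer(record_every))
  traj <- NULL
  if (record_every > 0) {
    tm <- res$trajectory
    n <- cg$n
    colnames(tm) <- c("t",
                      if (n) paste0("mrna_", seq_len(n)),
                      if (n) paste0("protein_", seq_len(n)),
                      "basic_tf", "signal", "phenotype")
    traj <- as.data.frame(tm)
  }
  list(
    final_phenotype = res$phenotype[1L],
    final_state = list(t = params$T_dev,
                       mrna = as.double(res$mrna[, 1L]),
                       protein = as.double(res$protein[, 1L]),
                       basic_tf = res$basic_tf[1L],
                       signal = res$signal[1L],
                       phenotype = res$phenotype[1L]),
    trajectory = traj
  )
}

#' Replicate developments of one genotype
#'
#' Runs `n` independent developments and returns the final phenotypes (and
#' optionally the final molecule counts).
#'
#' @inheritParams develop
#' @param n Number of replicate developments.
#' @param final_counts If `TRUE`, also return final mRNA/protein count
#'   matrices (genes x replicates).
#' @return A numeric vector of final phenotypes, or a list when
#'   `final_counts = TRUE`.
#' @export
develop_many <- function(g, n, signal = signal_spec(),
                         params = regulation_params(), seed = NULL,
                         final_counts = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cg <- compile_genotype(g)
  res <- cpp_develop(cg, signal_mode_code(signal$mode), signal$Pe,
                     as.integer(n), params, 0L)
  if (final_counts) {
    list(phenotype = res$phenotype, mrna = res$mrna, protein = res$protein,
         basic_tf = res$basic_tf, signal = res$signal)
  } else {
    res$phenotype
  }
}
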