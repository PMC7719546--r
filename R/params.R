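#' Regulation and tau-leap parameters
#'
#' All rate parameters of the developmental simulator.  Translation and
#' both decay rates are fixed for all genes, so mutations act on phenotype
#' only through transcriptional regulation.  The step size `tau` trades
#' speed against discretization error; `T_dev / tau` must be an integer
#' number of steps.
#'
#' @param tau Time step (min).
#' @param r_max Maximal transcription rate (mRNA/min).
#' @param K0 Base dissociation scale of a binding site (molecules) at zero
#'   mismatch.
#' @param lambda_mismatch Fold increase in dissociation per unit of binding
#'   mismatch.
#' @param basic_tf_input Input rate of the non-evolving basic transcription
#'   factor (molecules/min).
#' @param basic_tf_motif Motif the basic transcription factor binds
#'   (fixed; its inherent effect is +1).
#' @param translation_rate Proteins per mRNA per min.
#' @param mrna_decay,protein_decay Decay rates (1/min); the signal decays
#'   at `protein_decay`.
#' @param k_P Phenotype growth scale per protein, per unit phenotype
#'   effect, per min.
#' @param K_hill Dissociation constant of signal--protein cooperative
#'   binding (molecules).
#' @param T_dev Total development time (min).
#' @return A list of validated parameters.
#' @export
regulation_params <- function(tau = 0.5, r_max = 5, K0 = 100,
                              lambda_mismatch = 2, basic_tf_input = 10,
                              basic_tf_motif = 0L, translation_rate = 1,
                              mrna_decay = 0.2, protein_decay = 0.05,
                              k_P = 0.01, K_hill = 2e4, T_dev = 300) {
  p <- list(tau = tau, r_max = r_max, K0 = K0,
            lambda_mismatch = lambda_mismatch,
            basic_tf_input = basic_tf_input,
            basic_tf_motif = as.integer(basic_tf_motif),
            translation_rate = translation_rate,
            mrna_decay = mrna_decay, protein_decay = protein_decay,
            k_P = k_P, K_hill = K_hill, T_dev = T_dev)
  stopifnot(all(vapply(p[c("tau", "r_max", "K0", "lambda_mismatch",
                           "translation_rate", "mrna_decay",
                           "protein_decay", "k_P", "K_hill", "T_dev")],
                       function(x) is.numeric(x) && x > 0, logical(1))),
            p$basic_tf_input >= 0)
  steps <- p$T_dev / p$tau
  if (abs(steps - round(steps)) > 1e-9)
    stop("T_dev / tau must be an integer number of steps")
  p$n_steps <- as.integer(round(steps))
  p
}

#' Signal specification
#'
#' The only channel through which the environment enters development.  In
#' `"environmental"` mode the signal is input at a constant rate equal to
#' the environmental optimum `Pe` (an open-loop cue); in `"performance"`
#' mode at rate `|Pt - Pe|`, the current mismatch between the developing
#' phenotype and the optimum, recomputed at every step (a closed-loop,
#' negative-feedback cue); in `"none"` mode no signal is input and
#' development is independent of `Pe`.
#'
#' @param mode `"none"`, `"environmental"` or `"performance"`.
#' @param Pe Optimal phenotype of the current environment.
#' @return A list with `mode` and `Pe`.
#' @export
signal_spec <- function(mode = c("none", "environmental", "performance"),
                        Pe = 1000) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(Pe), length(Pe) == 1L, Pe >= 0)
  list(mode = mode, Pe = as.double(Pe))
}

signal_mode_code <- function(mode) {
  match(mode, c("none", "environmental", "performance")) - 1L
}

#' Map a treatment name to its signal mode
#' @param treatment Treatment name.
#' @return A signal mode string.
#' @export
treatment_mode <- function(treatment = c("no_signal", "environmental_signal",
                                         "performance_signal")) {
  treatment <- match.arg(treatment)
  c(no_signal = "none", environmental_signal = "environmental",
    performance_signal = "performance")[[treatment]]
}
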