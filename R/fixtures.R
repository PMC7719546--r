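# Hand-built demonstration circuits.  These embody the two plasticity
# mechanisms in their simplest form and are used throughout the tests:
#
#   constitutive      - a single phenotype gene driven by the basic TF;
#                       expression (and hence the phenotype) is identical
#                       in both environments.
#   env_toggle        - a signal-binding gene relays the environmental
#                       signal: its heterodimer is more active in the high
#                       environment (Hill saturation of Pe), activating a
#                       phenotype gene more strongly there.
#   perf_feedback     - the heterodimer of a performance-signal-binding
#                       gene drives the phenotype gene, so phenotype growth
#                       shuts down as |Pt - Pe| falls: a negative feedback
#                       loop that corrects stochastic excursions.
#   open_loop_matched - a constitutive circuit whose phenotype-catalysis
#                       effect is tuned so its mean final phenotype in the
#                       low environment matches perf_feedback's within 2%,
#                       isolating the feedback's effect on noise.
#
# Numeric constants were calibrated once by simulation (see the package
# vignette) and are fixed.

zero_sites <- function() {
  list(motif = rep(0L, N_SITES), effect = rep(0, N_SITES),
       mismatch = rep(0L, N_SITES))
}

fixture_gene <- function(kind, sites, target, inherent = 1,
                         phenotype_effect = NULL, hill_n = NULL,
                         lineage_id = 1L) {
  s <- zero_sites()
  for (i in seq_along(sites$motif)) {
    s$motif[i] <- sites$motif[i]
    s$effect[i] <- sites$effect[i]
    s$mismatch[i] <- sites$mismatch[i]
  }
  gene(kind, s$motif, s$effect, s$mismatch, inherent, target,
       phenotype_effect = phenotype_effect, hill_n = hill_n,
       lineage_id = lineage_id)
}

# An inert motif no fixture protein targets, so unused sites (cis effect 0,
# motif 0) never see the basic TF by accident -- they have zero effect
# anyway -- and fixture proteins never self-regulate.
INERT_MOTIF <- 19L

FIXTURE_CONST <- list(
  constitutive_pe = 1.879,       # mean final phenotype ~ 1000 (low env)
  toggle_hill_n = 4,
  toggle_cis = 6,
  toggle_mismatch = 5L,
  toggle_pe = 5.6,               # mean_low ~ 1000, mean_high ~ 1770
  feedback_hill_n = 2,
  feedback_cis = 3,
  feedback_pe = 2,               # mean ~ 983 with strong late shut-off
  open_loop_pe = 1.8477          # matched to perf_feedback's mean (+/- 2%)
)

#' Hand-built demonstration genotypes
#'
#' Four minimal circuits used to demonstrate the model's two plasticity
#' mechanisms: `"constitutive"` (basic-TF-driven phenotype gene, identical
#' in every environment), `"env_toggle"` (an environmental-signal relay
#' that expresses the phenotype gene more strongly in the high
#' environment), `"perf_feedback"` (a performance-signal relay forming a
#' negative feedback loop that slows phenotype growth as the phenotype
#' approaches the optimum), and `"open_loop_matched"` (a constitutive
#' circuit tuned to the same mean final phenotype as `perf_feedback`, for
#' like-for-like noise comparisons).
#'
#' @param name Fixture name.
#' @return A [genotype()].
#' @export
make_fixture <- function(name = c("constitutive", "env_toggle",
                                  "perf_feedback", "open_loop_matched")) {
  name <- match.arg(name)
  k <- FIXTURE_CONST
  tf_site <- function(effect) list(motif = 0L, effect = effect, mismatch = 0L)
  het_site <- function(effect, mismatch = 0L)
    list(motif = 1L, effect = effect, mismatch = mismatch)

  switch(name,
    constitutive = genotype(list(
      fixture_gene("phenotype",
                   list(motif = 0L, effect = 1, mismatch = 0L),
                   target = INERT_MOTIF,
                   phenotype_effect = k$constitutive_pe, lineage_id = 1L)
    )),
    env_toggle = genotype(list(
      fixture_gene("signal_binding", tf_site(1), target = 1L,
                   hill_n = k$toggle_hill_n, lineage_id = 1L),
      fixture_gene("phenotype",
                   het_site(k$toggle_cis, k$toggle_mismatch),
                   target = INERT_MOTIF,
                   phenotype_effect = k$toggle_pe, lineage_id = 2L)
    )),
    perf_feedback = genotype(list(
      fixture_gene("signal_binding", tf_site(1), target = 1L,
                   hill_n = k$feedback_hill_n, lineage_id = 1L),
      fixture_gene("phenotype", het_site(k$feedback_cis),
                   target = INERT_MOTIF,
                   phenotype_effect = k$feedback_pe, lineage_id = 2L)
    )),
    open_loop_matched = genotype(list(
      fixture_gene("phenotype",
                   list(motif = 0L, effect = 1, mismatch = 0L),
                   target = INERT_MOTIF,
                   phenotype_effect = k$open_loop_pe, lineage_id = 1L)
    ))
  )
}
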