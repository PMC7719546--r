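---
title: "The devonet model: stochastic network development, signals, and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The devonet model: stochastic network development, signals, and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devonet)
```

devonet simulates the development of a single quantitative phenotype by a
small gene-regulatory network inside one cell, and the evolution of
populations of such networks.  Its purpose is to study how the *mechanism*
of phenotypic plasticity — sensing the environment directly versus sensing
one's own performance — shapes developmental noise and the evolution of
plastic reaction norms.

## The developmental model

A genotype is an ordered list of genes of three kinds.  *Regulatory* genes
code for transcription factors that can only regulate transcription.
*Phenotype* genes also regulate, and in addition their proteins catalyze
growth of the phenotype.  *Signal-binding* genes code for proteins that
form an active heterodimer with an external signal molecule; the
heterodimer regulates transcription like any other factor.  Kinds never
change under mutation.

Each gene carries a cis-regulatory region of exactly `B = 20` binding
sites — each with a motif identity (20 possible motifs), a signed
cis-regulatory effect, and an integer binding-affinity mismatch — and a
coding region with the protein's inherent effect (activator > 0,
repressor < 0) and its target motif.

Transcription of gene $j$ is a Michaelis–Menten-like integration of
activator and repressor input over its sites.  A regulator species present
at $X$ copies occupies a site with dissociation constant
$K_0 \lambda^{\text{mismatch}}$ at rate
$\theta = X / (X + K_0\lambda^{\text{mismatch}})$, and each matching
site–regulator pair contributes the signed quantity
$s = \text{cis effect} \times \text{inherent effect} \times \theta$.  With
$A$ the sum of positive contributions and $R$ the magnitude sum of negative
ones,

$$ \text{rate}_j \;=\; r_{\max}\,\frac{A}{1 + A + R}, $$

and the rate is 0 when $A = 0$: genes need a bound activator to be
expressed.  Because of this, a non-evolving *basic transcription factor*
(inherent effect $+1$, fixed target motif) enters the cell at a constant
rate and can bootstrap expression.

Development runs for $T_{dev} = 300$ minutes of tau-leaping with step
$\tau = 0.5$ min: per step, each reaction channel (basic TF input, per-gene
transcription, per-mRNA translation, mRNA decay, protein decay, signal
input and signal decay) draws an independent Poisson count at its current
propensity, counts are updated simultaneously and clamped at zero.  The
phenotype grows deterministically from the current protein counts,
$\Delta P = \tau\, k_P \sum_i p_i \cdot e_i$ over phenotype genes $i$ with
catalysis effects $e_i$, and never decays (irreversible development).  All
developmental noise therefore originates in the discrete birth–death
randomness of molecule counts and propagates through the regulatory
network.

### Signals

The environment enters development only through the signal channel.  With
an *environmental signal*, signal molecules are input at constant rate
$P_e$, the optimum of the current environment — an open-loop cue.  With a
*performance signal*, the input rate is $|P_t - P_e|$, the current
mismatch between the developing phenotype and the optimum, recomputed at
every step — a closed-loop cue that implements a negative feedback during
development.  The signal decays at the protein decay rate.  Signal
molecules act only in complex with a signal-binding protein: with $S$
signal molecules, a signal-binding gene with Hill coefficient $n$ exposes
an effective fraction

$$ S_e = \frac{S^n}{K^n + S^n} $$

of its protein copies as active heterodimer (cooperative binding).  $n$ is
drawn uniformly on $[1, 5]$ at genotype construction.  The printed form of
$S_e$ is dimensionless, although it is described as an available
concentration; we implement it literally as a saturating availability
fraction multiplying the partner protein's copy number, and do not
rescale it.  Signal molecules are not consumed by complex formation.

### Defaults and their rationale

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.5 min | leap step; 600 steps per development |
| `r_max` | 5 /min | maximal transcription rate |
| `K0` | 100 | site dissociation scale at zero mismatch |
| `lambda_mismatch` | 2 | fold weakening per mismatch unit |
| `basic_tf_input` | 10 /min | basic TF supply (stationary count 200) |
| `translation_rate` | 1 /mRNA/min | fixed for all genes |
| `mrna_decay`, `protein_decay` | 0.2, 0.05 /min | fixed for all genes |
| `k_P` | 0.01 | phenotype growth scale |
| `K_hill` | 2×10⁴ | signal heterodimer dissociation constant |

Only the topology-level constants (20 sites, 20 motifs, $T_{dev}$, the two
optima, $\omega$, the mutation rates for duplication and deletion) are
fixed by the study design; the remaining kinetic constants are declared
package defaults, chosen so that (i) a constitutively expressed gene
reaches a stationary protein count of a few hundred copies, (ii) a
one-to-two-gene circuit can reach phenotypes of order 1000 within 300
minutes, and (iii) the stationary environmental-signal count in the low
environment ($P_e/\text{protein decay} = 2\times10^4$) sits exactly at the
Hill dissociation constant, so the two environments straddle the
half-saturation point of any signal-binding gene.  Halving `tau` does not
shift stationary means (tested); it inflates the stationary variance of a
birth–death species by the Euler factor $2/(2 - \delta\tau)$, about 5% at
the mRNA decay rate, which is accounted for where variances are compared.

## Mutation

Six mutation types act per genome replication: whole-gene duplication
(Poisson, $10^{-8}$ per genome), whole-gene deletion (Bernoulli, $10^{-7}$
per gene), and four regulatory-effect channels (each Bernoulli per gene,
default $10^{-5}$): perturbation of the inherent effect, a ±1 step of one
site's mismatch (reflecting at 0 and 10), re-targeting to one of the other
19 motifs, and perturbation of one site's cis effect.  Gaussian kernels
(sd 0.1, i.e. a tenth of the founder draw sd) are used for the two
continuous channels.  The four effect rates and kernels are package-level
design choices, configurable in `mutation_rates()`.  Duplicates are exact
copies appended at the end of the genome, keeping their lineage id.  The
signal-binding genes' coding fields (target motif, inherent effect) mutate
through the same channels; their Hill coefficients are fixed at founding.

## Evolution

Populations are haploid with nonoverlapping generations at constant size
$N$ (default 10,000; reduced presets use 100).  Each individual develops
once per generation — selection acts on realized phenotypes, which is what
makes developmental noise costly — and survives with Gaussian stabilizing
fitness $w = \exp[-\omega (P - P_e)^2]$, $\omega = 5\times10^{-5}$.
Reproduction is fitness-proportional multinomial resampling of parents
(clonal).  The model organisms are described as randomly mating
hermaphrodites, but with freely varying gene numbers recombination has no
canonical definition, and the questions addressed here do not hinge on it;
devonet therefore implements selection-only Wright–Fisher reproduction by
default, with an optional free-recombination mode (each gene lineage
inherited from one of two sampled parents by a fair coin flip) in
`next_generation()`.

Environments: `constant_low` ($P_e = 1000$), `constant_high`
($P_e = 3000$), or `spatial_heterogeneity`, where each individual is
assigned independently to either optimum with probability 1/2 every
generation (migration rate 0.5).

Founders: three regulatory and three phenotype genes (plus three
signal-binding genes in signal treatments), with cis and inherent effects
drawn N(0, 1), mismatches uniform on 0–5, catalysis effects |N(1, 0.3)|.
Candidate founders are rejection-sampled until the mean fitness over
`n_found = 1000` developments in the low environment (under the
treatment's signal mode) lies in (0.15, 0.25); the number of assay
developments is a package choice.  Averaging per-development fitnesses was
chosen over applying fitness to the mean phenotype: it is the quantity
selection actually sees, and the alternative is one line to change.  A
cheap 25-development pre-screen discards candidates whose rough mean
fitness is outside (0.04, 0.6) before the full assay; the bounds are wide
enough (±8 SE at the window edges) that accepted genotypes are unaffected.
Inverting the fitness formula puts an accepted founder's mean phenotype
near $|{\bar P} - 1000| \in (166.5, 194.8)$; developmental noise widens
this band outward (Jensen's inequality: for $P \sim N(\mu, \sigma^2)$,
$E[w] = \exp[-\omega d^2/(1{+}2\omega\sigma^2)]/\sqrt{1{+}2\omega\sigma^2}$),
by roughly 10% at typical noise levels, which the tests account for.

## Assays

* **Reaction norm** — mean final phenotype over `n_redevelop` independent
  redevelopments in each environment (50,000 at full scale), under the
  treatment's own signal mode in both environments (the signal is the only
  channel by which the environment can act, so the assay must keep it).
* **Plasticity** — a genotype is plastic when
  $|\bar P_{high} - \bar P_{low}| > \Delta P = 400$ (20% of the distance
  between the optima), a strict inequality; 100/200/800 are available
  alternatives.
* **Developmental noise** — the sample standard deviation (n−1
  denominator; at small test sizes the convention matters) of the
  low-environment redevelopments.

When an assay is given a seed, both environments replay the same random
stream.  This pairing makes the reaction norm of a signal-blind genotype
exactly flat and shrinks the sampling variance of the reaction-norm
difference; it leaves single-environment statistics untouched.

`summarize_experiment()` reports, per treatment-by-environment cell, the
fraction of replicates whose final most-common genotype is plastic — both
among all replicates and among those whose founder was not plastic, since
founders can start plastic — mean ± SE of noise split by plasticity class,
pairwise Welch t-tests on noise, and pairwise Fisher exact tests on the
plasticity fractions.  The regression analyses that can be run on these
tables (interaction OLS, ANCOVA on gene counts) are left to the user's
statistical environment; the tables contain everything they need.

## Demonstration circuits

`make_fixture()` builds four minimal circuits.  `constitutive` is a single
phenotype gene driven by the basic TF.  `env_toggle` relays the
environmental signal: its heterodimer is about twice as active in the high
environment (Hill saturation at $3K$ versus $K$), which a high-mismatch
site converts into a reaction-norm difference well above 400.
`perf_feedback` drives the phenotype gene through a performance-signal
heterodimer, so growth shuts down as $|P_t - P_e| \to 0$; trajectories that
run fast stall early and slow ones catch up, compressing the final
distribution.  `open_loop_matched` is the constitutive control tuned to
`perf_feedback`'s mean final phenotype within 2%, so their noise can be
compared like for like.  The numeric constants in these fixtures were
calibrated by simulation once and then frozen; at 1,200 redevelopments the
feedback circuit's noise (sd ≈ 27) is well below the matched open-loop
circuit's (sd ≈ 65).

```{r, eval = FALSE}
fb <- develop_many(make_fixture("perf_feedback"), 1000,
                   signal_spec("performance", 1000), seed = 1)
ol <- develop_many(make_fixture("open_loop_matched"), 1000,
                   signal_spec("none", 1000), seed = 1)
c(mean(fb), sd(fb), mean(ol), sd(ol))
```

## Scales, numerical choices, and limitations

The full design — 3 signal treatments × 2 environment models × 200
replicates at $N = 10{,}000$ for 100,000+ generations, with half of the
heterogeneous replicates extended to 200,000 — is enumerated by
`build_plan("paper")` and is intended for cluster execution (a single
replicate at that scale runs for weeks).  The package's own tests and the
reproduction script run the structurally identical reduced preset: $N =
100$, 300 generations, 10 replicates, 500 redevelopments per assay
environment.  At this scale the structural results (no plasticity without
a signal; adaptation toward the optimum; the two fixture mechanisms) are
reproducible in minutes on one CPU, while the quantitative fractions of
replicates that evolve plasticity in the signal treatments are
mutation-supply-limited and are *not* expected to match full-scale values.

What the synthetic study does and does not emulate: developmental noise
here is purely intrinsic (birth–death stochasticity of discrete molecule
counts); real organisms add extrinsic noise sources, cell–cell variation
and environmental microheterogeneity, so passing tests demonstrate the
mechanisms, not empirical effect sizes.  Other known simplifications:
single cell, single trait, irreversible phenotype growth, no recombination,
no diploidy, and no sequence-level representation of binding sites.

Numerical conventions worth knowing: ties for the most common genotype are
broken by first occurrence in population order; gene order matters for
genotype identity but not for regulation; an all-zero-fitness generation
raises an extinction error rather than resampling silently; empty
genotypes (possible through deletion) develop a phenotype of 0; counts are
clamped at zero after each leap; and every stage (founding, environment
assignment, development, reproduction, assays) draws from an independently
derived child seed, so any stage can be replayed in isolation from a
record's master seed.
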