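# Genotype representation: an ordered list of genes, each with a 20-site
# cis-regulatory region and a coding region.  Gene kinds never change under
# mutation; gene number changes only through duplication and deletion.

N_SITES <- 20L
N_MOTIFS <- 20L
GENE_KINDS <- c("regulatory", "phenotype", "signal_binding")

#' Construct a gene
#'
#' A gene has a cis-regulatory region of exactly 20 binding sites and a
#' coding region.  Each binding site carries a motif identity (one of 20
#' possible motifs), a signed cis-regulatory effect, and a binding-affinity
#' mismatch (an integer count of implicit amino-acid mismatches; larger
#' means weaker binding).  The coding region carries the protein's inherent
#' regulatory effect (activator if positive, repressor if negative) and the
#' motif it targets; phenotype genes additionally carry a positive
#' per-protein phenotype catalysis effect, and signal-binding genes a Hill
#' coefficient in \[1, 5\] for cooperative binding with the signal.
#'
#' @param kind One of `"regulatory"`, `"phenotype"`, `"signal_binding"`.
#' @param site_motif Integer vector of length 20, motif ids in `0:19`.
#' @param site_effect Numeric vector of length 20, signed cis effects.
#' @param site_mismatch Integer vector of length 20, mismatches in
#'   `0:mismatch_max`.
#' @param inherent_effect Signed scalar, the protein's regulatory effect.
#' @param target_motif Integer scalar in `0:19`, motif the protein binds.
#' @param phenotype_effect Positive scalar; required for phenotype genes,
#'   disallowed otherwise.
#' @param hill_n Scalar in `[1, 5]`; required for signal-binding genes,
#'   disallowed otherwise.
#' @param lineage_id Integer identifier used to track gene homology across
#'   duplications; copied verbatim when a gene is duplicated.
#' @param mismatch_max Maximum allowed mismatch (default 10).
#' @return A list with class-free gene fields, validated.
#' @export
gene <- function(kind, site_motif, site_effect, site_mismatch,
                 inherent_effect, target_motif,
                 phenotype_effect = NULL, hill_n = NULL,
                 lineage_id = NA_integer_, mismatch_max = 10L) {
  kind <- match.arg(kind, GENE_KINDS)
  g <- list(
    kind = kind,
    site_motif = as.integer(site_motif),
    site_effect = as.double(site_effect),
    site_mismatch = as.integer(site_mismatch),
    inherent_effect = as.double(inherent_effect)[1L],
    target_motif = as.integer(target_motif)[1L],
    phenotype_effect = if (is.null(phenotype_effect)) NA_real_ else as.double(phenotype_effect)[1L],
    hill_n = if (is.null(hill_n)) NA_real_ else as.double(hill_n)[1L],
    lineage_id = as.integer(lineage_id)[1L]
  )
  validate_gene(g, mismatch_max = mismatch_max)
  g
}

validate_gene <- function(g, mismatch_max = 10L) {
  stopifnot(
    g$kind %in% GENE_KINDS,
    length(g$site_motif) == N_SITES,
    length(g$site_effect) == N_SITES,
    length(g$site_mismatch) == N_SITES,
    all(g$site_motif >= 0L & g$site_motif < N_MOTIFS),
    all(g$site_mismatch >= 0L & g$site_mismatch <= mismatch_max),
    all(is.finite(g$site_effect)),
    is.finite(g$inherent_effect),
    g$target_motif >= 0L, g$target_motif < N_MOTIFS
  )
  if (g$kind == "phenotype") {
    if (!is.finite(g$phenotype_effect) || g$phenotype_effect <= 0)
      stop("phenotype genes require a positive phenotype_effect")
  } else if (is.finite(g$phenotype_effect)) {
    stop("phenotype_effect is only allowed on phenotype genes")
  }
  if (g$kind == "signal_binding") {
    if (!is.finite(g$hill_n) || g$hill_n < 1 || g$hill_n > 5)
      stop("signal-binding genes require hill_n in [1, 5]")
  } else if (is.finite(g$hill_n)) {
    stop("hill_n is only allowed on signal-binding genes")
  }
  invisible(g)
}

#' Construct a genotype from a list of genes
#'
#' A genotype is an ordered list of genes; order matters for identity (two
#' genotypes with the same genes in a different order are distinct) but not
#' for regulation, which is order-free.  A genotype may become empty in any
#' kind, or entirely, through deletions.
#'
#' @param genes List of genes built with [gene()].
#' @return An object of class `"genotype"`.
#' @seealso [random_genotype()], [mutate_genome()], [genotype_key()]
#' @export
genotype <- function(genes = list()) {
  for (g in genes) validate_gene(g)
  structure(genes, class = "genotype")
}

#' @export
`[.genotype` <- function(x, i) {
  structure(unclass(x)[i], class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  kinds <- gene_kinds(x)
  cat(sprintf("<genotype: %d genes (%d regulatory, %d phenotype, %d signal-binding)>\n",
              length(x),
              sum(kinds == "regulatory"),
              sum(kinds == "phenotype"),
              sum(kinds == "signal_binding")))
  invisible(x)
}

#' Gene kinds of a genotype
#' @param g A genotype.
#' @return Character vector of gene kinds, one per gene.
#' @export
gene_kinds <- function(g) {
  vapply(unclass(g), `[[`, character(1), "kind")
}

#' Count genes of each kind
#' @param g A genotype.
#' @return Named integer vector over the three kinds.
#' @export
gene_counts <- function(g) {
  k <- factor(gene_kinds(g), levels = GENE_KINDS)
  setNames(as.integer(table(k)), GENE_KINDS)
}

#' Distributions used to draw founder genes
#'
#' Founder genotypes are drawn at random and rejection-sampled to a target
#' mean-fitness window (see [found_population()]), so these distributions
#' must make moderately expressed networks reasonably likely.  Cis and
#' inherent effects are standard Gaussian, initial mismatches uniform on
#' `0:5`, and phenotype catalysis effects |N(1, 0.3)|.
#'
#' @param cis_sd SD of initial cis-regulatory effects.
#' @param inherent_sd SD of initial inherent regulatory effects.
#' @param mismatch_init_max Maximum initial binding mismatch.
#' @param phenotype_effect_mean,phenotype_effect_sd Mean and SD of the
#'   Gaussian whose absolute value gives the phenotype catalysis effect.
#' @param mismatch_max Hard upper bound on mismatches under mutation.
#' @return A list of prior settings.
#' @export
founder_priors <- function(cis_sd = 1, inherent_sd = 1,
                           mismatch_init_max = 5L,
                           phenotype_effect_mean = 1,
                           phenotype_effect_sd = 0.3,
                           mismatch_max = 10L) {
  list(cis_sd = cis_sd, inherent_sd = inherent_sd,
       mismatch_init_max = as.integer(mismatch_init_max),
       phenotype_effect_mean = phenotype_effect_mean,
       phenotype_effect_sd = phenotype_effect_sd,
       mismatch_max = as.integer(mismatch_max))
}

random_gene <- function(kind, priors, lineage_id) {
  gene(
    kind = kind,
    site_motif = sample.int(N_MOTIFS, N_SITES, replace = TRUE) - 1L,
    site_effect = rnorm(N_SITES, 0, priors$cis_sd),
    site_mismatch = sample.int(priors$mismatch_init_max + 1L, N_SITES,
                               replace = TRUE) - 1L,
    inherent_effect = rnorm(1, 0, priors$inherent_sd),
    target_motif = sample.int(N_MOTIFS, 1L) - 1L,
    phenotype_effect = if (kind == "phenotype")
      abs(rnorm(1, priors$phenotype_effect_mean, priors$phenotype_effect_sd)),
    hill_n = if (kind == "signal_binding") runif(1, 1, 5),
    lineage_id = lineage_id,
    mismatch_max = priors$mismatch_max
  )
}

#' Draw a random founder genotype
#'
#' Returns three regulatory and three phenotype genes; signal treatments add
#' three signal-binding genes whose Hill coefficients are drawn uniformly on
#' \[1, 5\].
#'
#' @param treatment `"no_signal"`, `"environmental_signal"` or
#'   `"performance_signal"`.
#' @param priors Initial-draw distributions, see [founder_priors()].
#' @param seed Optional integer seed set before drawing.
#' @return A [genotype()].
#' @export
random_genotype <- function(treatment = c("no_signal", "environmental_signal",
                                          "performance_signal"),
                            priors = founder_priors(), seed = NULL) {
  treatment <- match.arg(treatment)
  if (!is.null(seed)) set.seed(seed)
  kinds <- c(rep("regulatory", 3L), rep("phenotype", 3L))
  if (treatment != "no_signal") kinds <- c(kinds, rep("signal_binding", 3L))
  genes <- lapply(seq_along(kinds), function(i) random_gene(kinds[i], priors, i))
  genotype(genes)
}

#' Mutation rates and effect-size kernels
#'
#' Six mutation types act per genome replication: whole-gene duplication
#' (Poisson, per genome), whole-gene deletion (Bernoulli, per gene), and
#' four regulatory-effect channels (Bernoulli, per gene): perturbation of
#' the protein's inherent effect, a one-step change of one binding site's
#' affinity mismatch, re-targeting of the protein to another motif, and
#' perturbation of one binding site's cis effect.
#'
#' @param duplication Duplication rate per genome per replication.
#' @param deletion Deletion rate per gene per replication.
#' @param inherent_effect,binding_affinity,target_motif,cis_effect Rates of
#'   the four regulatory-effect channels, per gene per replication.
#' @param inherent_sd,cis_sd SDs of the additive Gaussian kernels applied to
#'   inherent and cis effects.
#' @param mismatch_max Reflecting upper bound for affinity-mismatch steps.
#' @return A list of rates and kernel settings.
#' @export
mutation_rates <- function(duplication = 1e-8, deletion = 1e-7,
                           inherent_effect = 1e-5, binding_affinity = 1e-5,
                           target_motif = 1e-5, cis_effect = 1e-5,
                           inherent_sd = 0.1, cis_sd = 0.1,
                           mismatch_max = 10L) {
  r <- list(duplication = duplication, deletion = deletion,
            inherent_effect = inherent_effect,
            binding_affinity = binding_affinity,
            target_motif = target_motif, cis_effect = cis_effect,
            inherent_sd = inherent_sd, cis_sd = cis_sd,
            mismatch_max = as.integer(mismatch_max))
  stopifnot(all(vapply(r[1:6], function(x) x >= 0, logical(1))))
  r
}

#' Apply one replication's worth of mutation to a genotype
#'
#' Event counts follow the configured rates: duplications Poisson per
#' genome, all other types Bernoulli per gene.  Gene kinds are preserved by
#' every channel; a duplicated gene is an exact copy appended at the end of
#' the genome with the same lineage id.  An empty genotype is returned
#' unchanged.  The returned genotype carries an integer attribute
#' `"mutation_events"` counting realized events by type.
#'
#' @param g A [genotype()].
#' @param rates See [mutation_rates()].
#' @return A genotype (the same object when no event occurred).
#' @export
mutate_genome <- function(g, rates = mutation_rates()) {
  n <- length(g)
  ev <- c(duplication = 0L, deletion = 0L, inherent_effect = 0L,
          binding_affinity = 0L, target_motif = 0L, cis_effect = 0L)
  if (n == 0L) {
    attr(g, "mutation_events") <- ev
    return(g)
  }
  n_dup <- rpois(1L, rates$duplication)
  n_del <- rbinom(1L, n, rates$deletion)
  n_inh <- rbinom(1L, n, rates$inherent_effect)
  n_aff <- rbinom(1L, n, rates$binding_affinity)
  n_tar <- rbinom(1L, n, rates$target_motif)
  n_cis <- rbinom(1L, n, rates$cis_effect)
  if (n_dup + n_del + n_inh + n_aff + n_tar + n_cis == 0L) {
    attr(g, "mutation_events") <- ev
    return(g)
  }
  genes <- unclass(g)
  attr(genes, "mutation_events") <- NULL
  attr(genes, "compiled") <- NULL

  if (n_inh > 0L) for (i in sample.int(n, n_inh)) {
    genes[[i]]$inherent_effect <- genes[[i]]$inherent_effect +
      rnorm(1, 0, rates$inherent_sd)
  }
  if (n_aff > 0L) for (i in sample.int(n, n_aff)) {
    b <- sample.int(N_SITES, 1L)
    m <- genes[[i]]$site_mismatch[b] + sample(c(-1L, 1L), 1L)
    # reflect at the boundaries 0 and mismatch_max
    if (m < 0L) m <- 1L
    if (m > rates$mismatch_max) m <- rates$mismatch_max - 1L
    genes[[i]]$site_mismatch[b] <- m
  }
  if (n_tar > 0L) for (i in sample.int(n, n_tar)) {
    others <- setdiff(0:(N_MOTIFS - 1L), genes[[i]]$target_motif)
    genes[[i]]$target_motif <- sample(others, 1L)
  }
  if (n_cis > 0L) for (i in sample.int(n, n_cis)) {
    b <- sample.int(N_SITES, 1L)
    genes[[i]]$site_effect[b] <- genes[[i]]$site_effect[b] +
      rnorm(1, 0, rates$cis_sd)
  }
  if (n_dup > 0L) {
    src <- sample.int(n, n_dup, replace = TRUE)
    genes <- c(genes, genes[src])
  }
  if (n_del > 0L) {
    del <- sample.int(n, n_del)   # deletions hit the pre-duplication genes
    genes <- genes[-del]
  }
  ev[] <- c(n_dup, n_del, n_inh, n_aff, n_tar, n_cis)
  out <- structure(genes, class = "genotype")
  attr(out, "mutation_events") <- ev
  out
}
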