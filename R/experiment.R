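# Orchestration of the signal-by-environment experimental design:
# enumerating replicates with deterministic seeds, running them resumably,
# writing diff-able TSV/JSON outputs, and summarizing.

hash_string <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(x) hash_string(paste(deparse(x), collapse = ""))

#' Experiment scale presets
#'
#' `"paper"` is the full-scale design: 200 replicates per cell, N = 10,000,
#' 100,000 generations (half of the spatially heterogeneous replicates
#' extended to 200,000), 50,000 redevelopments per assay environment.
#' `"desk"` is a small structurally identical preset that completes on one
#' CPU in minutes.
#'
#' @param scale `"paper"` or `"desk"`.
#' @return A named list of plan settings.
#' @export
experiment_preset <- function(scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  if (scale == "paper") {
    list(scale = "paper", replicates = 200L, pop_size = 10000L,
         generations = 100000L, extended_generations = 200000L,
         n_redevelop = 50000L, delta_P = 400, seed = 1L,
         treatments = c("no_signal", "environmental_signal",
                        "performance_signal"),
         environments = c("constant_low", "spatial_heterogeneity"))
  } else {
    list(scale = "desk", replicates = 2L, pop_size = 100L,
         generations = 300L, extended_generations = 600L,
         n_redevelop = 500L, delta_P = 400, seed = 1L,
         treatments = c("no_signal", "environmental_signal",
                        "performance_signal"),
         environments = c("constant_low", "spatial_heterogeneity"))
  }
}

PLAN_KEYS <- c("scale", "replicates", "pop_size", "generations",
               "extended_generations", "n_redevelop", "delta_P", "seed",
               "treatments", "environments")

#' Build an experiment plan
#'
#' Enumerates every replicate of the treatments-by-environments grid with a
#' deterministic per-replicate seed derived from the master seed.  In
#' spatially heterogeneous cells, half of the replicates (a deterministic
#' choice given the master seed) are extended to `extended_generations`.
#'
#' @param config A preset name (`"desk"`/`"paper"`), a named list of plan
#'   settings, or the path of a YAML file of plan settings.  Unknown keys
#'   and out-of-range values are rejected with an error naming the key.
#' @return An object of class `"experiment_plan"`: the validated settings,
#'   a data frame of replicates, and the plan hash.
#' @export
build_plan <- function(config = "desk") {
  if (is.character(config) && length(config) == 1L) {
    if (config %in% c("desk", "paper")) {
      cfg <- experiment_preset(config)
    } else {
      cfg <- yaml::read_yaml(config)
      base <- experiment_preset(if (identical(cfg$scale, "paper")) "paper" else "desk")
      cfg <- modifyList(base, cfg)
    }
  } else {
    cfg <- modifyList(experiment_preset("desk"), as.list(config))
  }
  unknown <- setdiff(names(cfg), PLAN_KEYS)
  if (length(unknown))
    stop("unknown plan key(s): ", paste(unknown, collapse = ", "))
  check_range <- function(key, lo) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo)
      stop(sprintf("plan key '%s' must be a number >= %g", key, lo))
  }
  check_range("replicates", 1); check_range("pop_size", 2)
  check_range("generations", 0); check_range("extended_generations", 0)
  check_range("n_redevelop", 2); check_range("delta_P", 1e-12)
  check_range("seed", 0)
  bad_t <- setdiff(cfg$treatments,
                   c("no_signal", "environmental_signal", "performance_signal"))
  if (length(bad_t)) stop("plan key 'treatments': unknown value(s) ",
                          paste(bad_t, collapse = ", "))
  bad_e <- setdiff(cfg$environments,
                   c("constant_low", "constant_high", "spatial_heterogeneity"))
  if (length(bad_e)) stop("plan key 'environments': unknown value(s) ",
                          paste(bad_e, collapse = ", "))

  grid <- expand.grid(treatment = cfg$treatments,
                      environment = cfg$environments,
                      replicate = seq_len(cfg$replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$treatment, grid$environment, grid$replicate), ]
  rownames(grid) <- NULL
  grid$generations <- as.integer(cfg$generations)

  # deterministic choice of which heterogeneous replicates run longer
  het <- grid$environment == "spatial_heterogeneity"
  if (any(het) && cfg$extended_generations > cfg$generations) {
    for (tr in unique(grid$treatment)) {
      idx <- which(het & grid$treatment == tr)
      set.seed(derive_seed(cfg$seed, paste0("extend:", tr)))
      ext <- sample(idx, length(idx) %/% 2L)
      grid$generations[ext] <- as.integer(cfg$extended_generations)
    }
  }
  grid$seed <- vapply(seq_len(nrow(grid)), function(i)
    derive_seed(cfg$seed, paste(grid$treatment[i], grid$environment[i],
                                grid$replicate[i], sep = ":")), integer(1))
  structure(list(config = cfg, replicates = grid,
                 hash = config_hash(cfg[order(names(cfg))])),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan %s: %d replicates (%d treatments x %d environments x %d), N = %d, hash %s>\n",
              x$config$scale, nrow(x$replicates),
              length(x$config$treatments), length(x$config$environments),
              x$config$replicates, x$config$pop_size, x$hash))
  invisible(x)
}

replicate_config <- function(plan, i) {
  row <- plan$replicates[i, ]
  evolution_config(
    N = plan$config$pop_size, generations = row$generations,
    environment = row$environment, treatment = row$treatment,
    assay = assay_config(n_redevelop = plan$config$n_redevelop,
                         delta_P = plan$config$delta_P))
}

rep_dir <- function(out_dir, row) {
  file.path(out_dir, paste(row$treatment, row$environment, sep = "-"),
            sprintf("rep%03d", row$replicate))
}

write_tsv_commented <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_commented <- function(path) {
  read.delim(path, comment.char = "#", quote = "", stringsAsFactors = FALSE)
}

#' Write one simulation record to a replicate directory
#'
#' Emits `record.tsv` (one row per sampled generation), `result.tsv` (the
#' replicate-level outcome: founder and final assays, gene counts), and the
#' founder/final genotype JSONs.  All files carry the config hash and seed
#' in header comments so any row is reproducible in isolation.
#'
#' @param record A `simulation_record`.
#' @param dir Output directory (created if needed).
#' @param hash Config/plan hash recorded in the headers.
#' @return `dir`, invisibly.
#' @export
write_record <- function(record, dir, hash = config_hash(record$config)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c("devonet record v1",
           paste0("config_hash: ", hash),
           paste0("seed: ", record$seed))
  fa <- record$founder_assay; la <- record$final_assay
  result <- data.frame(
    treatment = record$config$treatment,
    environment = record$config$environment,
    N = record$config$N, generations = record$config$generations,
    seed = record$seed,
    founder_mean_fitness = record$founder_mean_fitness,
    founder_mean_low = fa$mean_low, founder_mean_high = fa$mean_high,
    founder_sd_low = fa$sd_low, founder_plastic = fa$is_plastic,
    final_mean_low = la$mean_low, final_mean_high = la$mean_high,
    final_sd_low = la$sd_low, final_plastic = la$is_plastic,
    n_redevelop = la$n_redevelop,
    genes_regulatory = record$gene_counts[["regulatory"]],
    genes_phenotype = record$gene_counts[["phenotype"]],
    genes_signal_binding = record$gene_counts[["signal_binding"]],
    stringsAsFactors = FALSE)
  write_tsv_commented(result, file.path(dir, "result.tsv"), hdr)
  write_tsv_commented(record$samples, file.path(dir, "record.tsv"), hdr)
  write_genotype(record$founder, file.path(dir, "founder.json"))
  write_genotype(record$final_genotype, file.path(dir, "final.json"))
  invisible(dir)
}

#' Read a replicate directory back as a (light) simulation record
#'
#' Reconstructs the fields needed by [summarize_experiment()] from
#' `result.tsv`, `record.tsv` and the genotype JSONs.
#'
#' @param dir A replicate directory written by [write_record()].
#' @return An object of class `"simulation_record"`.
#' @export
read_record <- function(dir) {
  res <- read_tsv_commented(file.path(dir, "result.tsv"))
  structure(list(
    config = list(treatment = res$treatment, environment = res$environment,
                  N = res$N, generations = res$generations),
    seed = res$seed,
    founder = read_genotype(file.path(dir, "founder.json")),
    founder_mean_fitness = res$founder_mean_fitness,
    founder_assay = structure(list(mean_low = res$founder_mean_low,
                                   mean_high = res$founder_mean_high,
                                   sd_low = res$founder_sd_low,
                                   is_plastic = res$founder_plastic,
                                   n_redevelop = res$n_redevelop),
                              class = "assay_result"),
    final_genotype = read_genotype(file.path(dir, "final.json")),
    final_assay = structure(list(mean_low = res$final_mean_low,
                                 mean_high = res$final_mean_high,
                                 sd_low = res$final_sd_low,
                                 is_plastic = res$final_plastic,
                                 n_redevelop = res$n_redevelop),
                            class = "assay_result"),
    samples = read_tsv_commented(file.path(dir, "record.tsv")),
    gene_counts = c(regulatory = res$genes_regulatory,
                    phenotype = res$genes_phenotype,
                    signal_binding = res$genes_signal_binding)
  ), class = "simulation_record")
}

#' Run an experiment plan
#'
#' Runs every replicate of the plan sequentially and resumably: a replicate
#' whose `result.tsv` already exists is never re-run or overwritten, and a
#' replicate that fails is logged to `failures.tsv` and quarantined without
#' aborting the plan.  Finishes by summarizing all completed replicates
#' (see [summarize_experiment()]) into `summary.tsv`, `noise_tests.tsv` and
#' `plasticity_tests.tsv`.
#'
#' @param plan An [build_plan()] result.
#' @param out_dir Writable output directory.
#' @param quiet Suppress per-replicate progress lines.
#' @return The summary list, invisibly.
#' @export
run_plan <- function(plan, out_dir, quiet = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failures <- list()
  for (i in seq_len(nrow(plan$replicates))) {
    row <- plan$replicates[i, ]
    dir <- rep_dir(out_dir, row)
    if (file.exists(file.path(dir, "result.tsv"))) next
    if (!quiet)
      message(sprintf("[%d/%d] %s / %s rep %d (seed %d)", i,
                      nrow(plan$replicates), row$treatment, row$environment,
                      row$replicate, row$seed))
    rec <- tryCatch(
      run_simulation(replicate_config(plan, i), seed = row$seed),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        treatment = row$treatment, environment = row$environment,
        replicate = row$replicate, seed = row$seed,
        error = conditionMessage(rec), stringsAsFactors = FALSE)
      next
    }
    write_record(rec, dir, hash = plan$hash)
  }
  if (length(failures))
    write_tsv_commented(do.call(rbind, failures),
                        file.path(out_dir, "failures.tsv"),
                        c("devonet failures v1", paste0("plan_hash: ", plan$hash)))
  dirs <- list.files(out_dir, pattern = "^result\\.tsv$", recursive = TRUE,
                     full.names = TRUE)
  records <- lapply(dirname(dirs), read_record)
  summ <- summarize_experiment(records)
  hdr <- c("devonet summary v1", paste0("plan_hash: ", plan$hash))
  write_tsv_commented(summ$summary, file.path(out_dir, "summary.tsv"), hdr)
  if (!is.null(summ$noise_tests))
    write_tsv_commented(summ$noise_tests,
                        file.path(out_dir, "noise_tests.tsv"), hdr)
  if (!is.null(summ$plasticity_tests))
    write_tsv_commented(summ$plasticity_tests,
                        file.path(out_dir, "plasticity_tests.tsv"), hdr)
  invisible(summ)
}
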