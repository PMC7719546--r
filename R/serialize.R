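# Canonical serialization.  A genotype's identity is equality of its
# canonical serialization: every field, including gene order and lineage
# ids, is part of identity.  Floats are rendered with 17 significant
# digits, which round-trips IEEE doubles bit-exactly.

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

gene_key <- function(gn) {
  paste(
    gn$kind,
    gn$target_motif,
    fmt17(gn$inherent_effect),
    fmt17(gn$phenotype_effect),
    fmt17(gn$hill_n),
    gn$lineage_id,
    paste(gn$site_motif, collapse = ","),
    paste(fmt17(gn$site_effect), collapse = ","),
    paste(gn$site_mismatch, collapse = ","),
    sep = "|"
  )
}

#' Canonical text key of a genotype
#'
#' Equal genotypes map to equal keys and any field difference (including a
#' reordering of genes) yields a different key.  Used to tabulate the most
#' common genotype in a population.
#'
#' @param g A [genotype()].
#' @return A single string.
#' @export
genotype_key <- function(g) {
  paste(vapply(unclass(g), gene_key, character(1)), collapse = "||")
}

#' Serialize a genotype to JSON
#'
#' Explicit field names, a format/version tag, and floats written with 17
#' significant digits so that the round trip through
#' [genotype_from_json()] is bit-exact.  (The JSON text is written
#' directly rather than through a generic encoder, which would round
#' doubles to 15 digits.)
#'
#' @param g A [genotype()].
#' @return A JSON string.
#' @export
genotype_json <- function(g) {
  gene_txt <- vapply(unclass(g), function(gn) {
    parts <- c(
      sprintf('"kind":"%s"', gn$kind),
      sprintf('"site_motif":[%s]', paste(gn$site_motif, collapse = ",")),
      sprintf('"site_effect":[%s]',
              paste(fmt17(gn$site_effect), collapse = ",")),
      sprintf('"site_mismatch":[%s]', paste(gn$site_mismatch, collapse = ",")),
      sprintf('"inherent_effect":%s', fmt17(gn$inherent_effect)),
      sprintf('"target_motif":%d', gn$target_motif),
      sprintf('"lineage_id":%d', gn$lineage_id),
      if (is.finite(gn$phenotype_effect))
        sprintf('"phenotype_effect":%s', fmt17(gn$phenotype_effect)),
      if (is.finite(gn$hill_n)) sprintf('"hill_n":%s', fmt17(gn$hill_n))
    )
    paste0("{", paste(parts, collapse = ","), "}")
  }, character(1))
  sprintf('{"format":"devonet-genotype","version":1,"genes":[%s]}',
          paste(gene_txt, collapse = ","))
}

#' Deserialize a genotype from JSON
#'
#' Parsed with the YAML parser (JSON is a YAML subset), which reads
#' numbers at full double precision.
#'
#' @param txt A JSON string produced by [genotype_json()].
#' @return A [genotype()].
#' @export
genotype_from_json <- function(txt) {
  x <- yaml::yaml.load(txt)
  if (!identical(x$format, "devonet-genotype"))
    stop("not a devonet genotype serialization")
  genes <- lapply(x$genes, function(gn) {
    gene(
      kind = gn$kind,
      site_motif = unlist(gn$site_motif),
      site_effect = unlist(gn$site_effect),
      site_mismatch = unlist(gn$site_mismatch),
      inherent_effect = gn$inherent_effect,
      target_motif = gn$target_motif,
      phenotype_effect = gn$phenotype_effect,
      hill_n = gn$hill_n,
      lineage_id = gn$lineage_id
    )
  })
  genotype(genes)
}

#' Write / read a genotype JSON file
#' @param g A [genotype()].
#' @param path File path.
#' @return `read_genotype` returns a [genotype()]; `write_genotype` returns
#'   `path` invisibly.
#' @export
write_genotype <- function(g, path) {
  writeLines(genotype_json(g), path)
  invisible(path)
}

#' @rdname write_genotype
#' @export
read_genotype <- function(path) {
  genotype_from_json(paste(readLines(path), collapse = "\n"))
}

# Deterministic child seeds below 2^31, so that founding, environment
# assignment, development and reproduction can be re-run in isolation.
derive_seed <- function(master, stream) {
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.double(master) %% 2147483647 * 69069 + h + 1) %% 2147483647)
}
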