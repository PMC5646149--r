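#' Derive a child seed from a scenario seed
#'
#' Deterministic seed derivation so every stochastic stage of a scenario
#' consumes its own named sub-seed: re-running any stage in isolation with
#' its logged seed reproduces its output. Values stay below 2^31.
#'
#' @param seed integer master seed.
#' @param ... integer stage/replicate indices.
#' @return a single integer seed.
#' @export
child_seed <- function(seed, ...) {
  x <- as.double(seed %% 2147483647)
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  }
  as.integer(x) + 1L
}

## ---- IMPUTE hap/legend/sample -------------------------------------------

#' Write haplotypes as an IMPUTE hap/legend/sample triplet
#'
#' `.hap`: one row per variant, one 0/1 column per haplotype;
#' `.legend`: header `id position a0 a1`; `.sample`: one row per diploid
#' individual (consecutive haplotype columns form an individual unless a
#' pairing is given).
#'
#' @param haps a `haplotype_matrix`.
#' @param prefix path prefix; files `<prefix>.hap`, `<prefix>.legend`,
#'   `<prefix>.sample` are written.
#' @param pairs optional two-column matrix of haplotype indices defining
#'   individuals (defaults to consecutive pairing).
#' @return the prefix, invisibly.
#' @export
write_hap_legend_sample <- function(haps, prefix, pairs = NULL) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  n <- nrow(haps$alleles)
  if (is.null(pairs)) {
    if (n %% 2L != 0L) stop("odd number of haplotypes; supply pairs")
    pairs <- matrix(seq_len(n), ncol = 2L, byrow = TRUE)
  }
  ord <- as.integer(t(pairs))
  M <- t(haps$alleles[ord, , drop = FALSE])   # sites x haplotypes
  utils::write.table(M, paste0(prefix, ".hap"), sep = " ",
                     row.names = FALSE, col.names = FALSE)
  legend <- data.frame(id = paste0("snp", seq_along(haps$positions)),
                       position = haps$positions, a0 = "A", a1 = "G")
  utils::write.table(legend, paste0(prefix, ".legend"), sep = " ",
                     row.names = FALSE, quote = FALSE)
  samp <- data.frame(ID_1 = paste0("ind", seq_len(nrow(pairs))),
                     ID_2 = paste0("ind", seq_len(nrow(pairs))),
                     missing = 0,
                     hap_a = haps$labels[pairs[, 1L]],
                     hap_b = haps$labels[pairs[, 2L]])
  utils::write.table(samp, paste0(prefix, ".sample"), sep = " ",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read an IMPUTE hap/legend/sample triplet
#'
#' @param prefix path prefix used by [write_hap_legend_sample].
#' @return a `haplotype_matrix`; the diploid pairing is attached as
#'   attribute `pairs`.
#' @export
read_hap_legend_sample <- function(prefix) {
  M <- as.matrix(utils::read.table(paste0(prefix, ".hap")))
  legend <- utils::read.table(paste0(prefix, ".legend"), header = TRUE)
  samp <- utils::read.table(paste0(prefix, ".sample"), header = TRUE)
  labels <- as.character(t(samp[, c("hap_a", "hap_b")]))
  if (length(labels) != ncol(M))
    labels <- paste0("h", seq_len(ncol(M)))
  haps <- haplotype_matrix(t(M), legend$position, labels)
  attr(haps, "pairs") <- matrix(seq_len(ncol(M)), ncol = 2L, byrow = TRUE)
  haps
}

## ---- phased VCF ---------------------------------------------------------

#' Write a phased VCF of a haplotype matrix
#'
#' Minimal VCFv4.2 with 1-based positions, alleles A/G, and phased GT
#' fields ("a|b"); consecutive haplotypes (or the supplied pairing) form
#' the diploid samples.
#'
#' @param haps a `haplotype_matrix`.
#' @param path output path.
#' @param pairs optional two-column matrix of haplotype indices.
#' @export
write_phased_vcf <- function(haps, path, pairs = NULL) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  n <- nrow(haps$alleles)
  if (is.null(pairs)) {
    if (n %% 2L != 0L) stop("odd number of haplotypes; supply pairs")
    pairs <- matrix(seq_len(n), ncol = 2L, byrow = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       paste0("ind", seq_len(nrow(pairs)))),
                     collapse = "\t")), con)
  A <- haps$alleles
  for (j in seq_along(haps$positions)) {
    gt <- paste0(A[pairs[, 1L], j], "|", A[pairs[, 2L], j])
    writeLines(paste(c("1", haps$positions[j], paste0("snp", j), "A", "G",
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phased VCF into a haplotype matrix
#'
#' Only biallelic SNVs with phased ("|") GT fields are accepted; an
#' unphased separator ("/") raises a parse error naming the line.
#'
#' @param path VCF file path.
#' @return a `haplotype_matrix` (two rows per sample, suffixed `_a`/`_b`),
#'   with the diploid pairing attached as attribute `pairs`.
#' @export
read_phased_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t")[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[seq_along(lines) > hdr]
  body <- body[nzchar(body)]
  pos <- integer(length(body))
  alle <- matrix(0L, 2L * length(samples), length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1L]]
    pos[i] <- as.integer(f[2L])
    gt <- f[-(1:9)]
    if (any(grepl("/", gt, fixed = TRUE)))
      stop(sprintf("unphased genotype at line %d (use '|' separators)",
                   hdr + i))
    sp <- strsplit(gt, "|", fixed = TRUE)
    alle[, i] <- as.integer(unlist(sp))
  }
  labels <- as.character(t(outer(samples, c("_a", "_b"), paste0)))
  haps <- haplotype_matrix(alle, pos, labels)
  attr(haps, "pairs") <- matrix(seq_len(2L * length(samples)),
                                ncol = 2L, byrow = TRUE)
  haps
}

## ---- IMPUTE2-style .gen output ------------------------------------------

#' Write genotype posteriors as IMPUTE2-style .gen probability triplets
#'
#' One row per imputed variant: `id rsid position a0 a1` followed by the
#' genotype probability triplet (P0 P1 P2) of every study individual.
#'
#' @param posterior a `genotype_posterior`.
#' @param positions bp positions of all sites in the cohort (the masked
#'   subset is selected internally).
#' @param path output path.
#' @export
write_gen <- function(posterior, positions, path) {
  stopifnot(inherits(posterior, "genotype_posterior"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(posterior$sites)) {
    j <- posterior$sites[k]
    trip <- as.vector(t(posterior$probs[, k, ]))
    writeLines(paste(c("imp", paste0("snp", j), positions[j], "A", "G",
                       sprintf("%.6g", trip)),
                     collapse = " "), con)
  }
  invisible(path)
}

## ---- scenario configuration (YAML) --------------------------------------

#' Read a scenario configuration file
#'
#' Structured YAML with the keys `n_haplotypes`, `n_sites`, `seq_length_bp`,
#' `n_e`, `mu`, `alpha`, `growth_onset_years`, `beta`, `split_time_years`,
#' `study_fraction`, `measured_fraction`, `seed`, and the scenario-runner
#' keys `n_sim_replicates`, `n_site_selections`, `n_trees`, `methods`,
#' `delta_generations`. Missing keys fall back to the baseline defaults.
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scenario_config, y)
}

#' Write a scenario configuration file
#'
#' @param config a `scenario_config`.
#' @param path output YAML path.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
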