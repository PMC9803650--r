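#' Configuration for the synthetic two-group InDel dataset
#'
#' Defines the study conditions the simulator emulates: two groups of diploid
#' samples (default 7 + 7) re-sequenced against a reference that belongs to
#' group B, with planted between-group fixed ("diagnostic") InDels, shared and
#' group-private polymorphic InDels, per-genotype missingness, and a gene
#' annotation dense enough that most variants fall in genic context.
#'
#' @param seed integer seed; identical seed + config gives byte-identical
#'   outputs.
#' @param n_chromosomes number of chromosomes to simulate.
#' @param chrom_length length of each chromosome in bp.
#' @param n_group_a,n_group_b diploid sample counts per group. Group A is the
#'   non-reference taxon (hill pigeon in the motivating study), group B the
#'   taxon the reference assembly belongs to (feral/domestic pigeon).
#' @param n_diagnostic number of planted between-group fixed InDels.
#' @param n_shared_polymorphic InDels segregating within both groups.
#' @param n_private_polymorphic InDels segregating within exactly one group.
#' @param indel_min_bp,indel_max_bp planted InDel length range; lengths are
#'   drawn uniformly so every marker tier (>50, >40, >34, >20 bp) is populated.
#' @param missing_rate per-genotype probability of masking to `./.`.
#' @param dropout_rate default per-band allelic dropout probability used by the
#'   in-silico genotyping stage.
#' @param gene_density genes per Mb for the simulated annotation.
#' @param variant_spacing minimum distance between planted variants (bp); the
#'   default keeps each 150-400 bp amplicon over a single planted InDel.
#' @param edge_margin minimum distance of a planted variant from either
#'   chromosome end (bp), so flanking primers always fit.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 200000L,
                              n_group_a = 7L,
                              n_group_b = 7L,
                              n_diagnostic = 50L,
                              n_shared_polymorphic = 100L,
                              n_private_polymorphic = 100L,
                              indel_min_bp = 5L,
                              indel_max_bp = 60L,
                              missing_rate = 0,
                              dropout_rate = 0,
                              gene_density = 100,
                              variant_spacing = 500L,
                              edge_margin = 500L) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_group_a = as.integer(n_group_a),
    n_group_b = as.integer(n_group_b),
    n_diagnostic = as.integer(n_diagnostic),
    n_shared_polymorphic = as.integer(n_shared_polymorphic),
    n_private_polymorphic = as.integer(n_private_polymorphic),
    indel_min_bp = as.integer(indel_min_bp),
    indel_max_bp = as.integer(indel_max_bp),
    missing_rate = as.numeric(missing_rate),
    dropout_rate = as.numeric(dropout_rate),
    gene_density = as.numeric(gene_density),
    variant_spacing = as.integer(variant_spacing),
    edge_margin = as.integer(edge_margin)
  )
  counts <- c("n_chromosomes", "n_group_a", "n_group_b", "n_diagnostic",
              "n_shared_polymorphic", "n_private_polymorphic")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop("simulation_config: '", f, "' must be a non-negative count")
    }
  }
  if (cfg$n_group_a < 1L || cfg$n_group_b < 1L) {
    stop("simulation_config: both groups need at least one sample")
  }
  if (cfg$chrom_length < 1000L) stop("simulation_config: chrom_length too small")
  if (cfg$indel_min_bp < 1L) stop("simulation_config: indel_min_bp must be >= 1")
  if (cfg$indel_max_bp < cfg$indel_min_bp) {
    stop("simulation_config: indel_max_bp must be >= indel_min_bp")
  }
  for (f in c("missing_rate", "dropout_rate")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("simulation_config: '", f, "' must be a probability in [0, 1]")
    }
  }
  if (cfg$gene_density < 0) stop("simulation_config: gene_density must be >= 0")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:",
      x$n_chromosomes, "x", x$chrom_length, "bp;",
      x$n_group_a, "+", x$n_group_b, "samples;",
      x$n_diagnostic, "diagnostic /", x$n_shared_polymorphic, "shared /",
      x$n_private_polymorphic, "private InDels of",
      paste0("[", x$indel_min_bp, ",", x$indel_max_bp, "] bp;"),
      "missing_rate", x$missing_rate, "\n")
  invisible(x)
}
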