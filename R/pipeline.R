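#' Run the full marker-discovery pipeline on synthetic data
#'
#' Orchestrates the five stages end to end: (1) simulate a two-group dataset
#' (reference + gene models + planted InDels + F1 crosses) and write it to
#' standard formats; (2) load the VCF back and scan for group-diagnostic loci;
#' (3) annotate all loci by genomic context; (4) design PCR marker candidates;
#' (5) genotype every parental and F1 individual in silico and evaluate the
#' marker panel. All randomness derives from `config$seed`, so a rerun with an
#' identical config reproduces byte-identical outputs.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory for stage files.
#' @param max_missing missingness policy for the diagnostic scan.
#' @param constraints a [primer_constraints()].
#' @param gel a [gel_model()].
#' @param n_f1 number of simulated F1 offspring (drawn from `n_f1`/2 parental
#'   pairs, two chicks per pair).
#' @return a list of class `pipeline_result` with all stage outputs and a
#'   `manifest` describing the run.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = tempfile(),
                         max_missing = 0L,
                         constraints = primer_constraints(),
                         gel = gel_model(),
                         n_f1 = 8L) {
  stopifnot(inherits(config, "simulation_config"), n_f1 %% 2L == 0L)
  stages <- character(0)

  # stage 1: simulate + write
  ref <- simulate_reference(config)
  planted <- plant_variants(ref, config)
  paths <- write_outputs(planted$matrix, planted$truth, ref, out_dir)
  n_pairs <- n_f1 %/% 2L
  if (config$n_group_a < n_pairs || config$n_group_b < n_pairs) {
    stop("run_pipeline: need at least ", n_pairs, " samples per group for ",
         n_f1, " F1 offspring")
  }
  locus_ids <- paste(planted$matrix$loci$chrom, planted$matrix$loci$pos,
                     sep = ":")
  f1 <- sapply(seq_len(n_f1), function(k) {
    pair <- (k + 1L) %/% 2L
    pa <- setNames(planted$matrix$gt[, paste0("A", pair)], locus_ids)
    pb <- setNames(planted$matrix$gt[, paste0("B", pair)], locus_ids)
    simulate_f1(pa, pb, seed = derive_seed(config$seed, 100L + k))
  })
  colnames(f1) <- sprintf("F1_%d", seq_len(n_f1))
  f1_path <- file.path(out_dir, "genotypes_f1.tsv")
  write.table(data.frame(locus = locus_ids, f1, check.names = FALSE),
              f1_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f1 = f1_path)
  stages <- c(stages, "simulate")

  # stage 2: scan the written VCF (round trip through the standard format)
  matrix <- load_matrix(paths[["vcf"]], paths[["groups"]], quiet = TRUE)
  calls <- scan_diagnostic(matrix, max_missing = max_missing)
  calls_path <- file.path(out_dir, "diagnostic_calls.tsv")
  write_diagnostic_calls(calls, calls_path)
  sample_summary <- summarize_samples(matrix)
  write.table(sample_summary, file.path(out_dir, "sample_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "scan")

  # stage 3: annotate all loci
  annotated <- annotate_indels(matrix$loci, ref$genes)
  cat_summary <- summarize_categories(annotated)
  write.table(annotated, file.path(out_dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cat_summary, file.path(out_dir, "annotation_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "annotate")

  # stage 4: design marker candidates
  candidates <- design_candidates(calls, ref, constraints)
  write.table(as.data.frame(candidates), file.path(out_dir, "markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "design")

  # stage 5: in-silico genotyping of parents + F1s at designed markers
  idx <- candidates$locus_index
  geno <- cbind(matrix$gt[idx, , drop = FALSE], f1[idx, , drop = FALSE])
  classes <- setNames(
    c(ifelse(unname(matrix$groups) == "A", "parental_A", "parental_B"),
      rep("F1", n_f1)),
    c(matrix$samples, colnames(f1)))
  panel <- evaluate_marker_panel(candidates, geno, classes, gel = gel,
                                 dropout_rate = config$dropout_rate,
                                 seed = derive_seed(config$seed, 200L))
  write.table(panel$per_marker, file.path(out_dir, "panel_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel$calls, file.path(out_dir, "panel_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "genotype")

  manifest <- list(
    seed = config$seed,
    stages = stages,
    n_loci = nrow(matrix$loci),
    n_diagnostic = nrow(calls),
    n_designed = nrow(candidates),
    n_accepted = sum(panel$per_marker$accepted),
    paths = as.list(c(paths, calls = calls_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(list(config = config, out_dir = out_dir, reference = ref,
                 truth = planted$truth, matrix = matrix, calls = calls,
                 sample_summary = sample_summary, annotated = annotated,
                 annotation_summary = cat_summary, candidates = candidates,
                 f1_genotypes = f1, panel = panel, manifest = manifest),
            class = "pipeline_result")
}

#' Summarize a pipeline run as a funnel report
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @return a list of class `pipeline_report`: `funnel` (stage, count; counts
#'   are monotonically non-increasing), `tiers`, `annotation_summary` and
#'   `per_marker`.
#' @export
pipeline_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  m <- result$manifest
  funnel <- data.frame(
    stage = c("indel_loci", "diagnostic", "designed", "accepted"),
    count = c(m$n_loci, m$n_diagnostic, m$n_designed, m$n_accepted),
    stringsAsFactors = FALSE)
  structure(list(funnel = funnel,
                 tiers = tier_counts(result$candidates),
                 annotation_summary = result$annotation_summary,
                 per_marker = result$panel$per_marker),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Marker-discovery funnel:\n")
  print(x$funnel, row.names = FALSE)
  cat("\nCandidates per InDel-length tier:\n")
  print(x$tiers, row.names = FALSE)
  cat("\nMarker panel:\n")
  print(x$per_marker[, c("marker_id", "tier", "n_correct",
                         "n_dropout_suspect", "n_fail", "accepted")],
        row.names = FALSE)
  invisible(x)
}
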