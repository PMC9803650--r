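#' Grouped genotype matrix
#'
#' Container for per-sample diploid genotypes at InDel loci together with the
#' sample-to-group assignment. Genotypes are stored as VCF-style strings
#' (`"0/0"`, `"0/1"`, `"./."`); half-calls such as `"0/."` are treated as
#' missing by all downstream operations, since they cannot establish
#' homozygosity.
#'
#' @param loci data.frame with columns chrom, pos, ref, alt, indel_length_bp,
#'   indel_type; one row per (decomposed, biallelic) InDel locus.
#' @param gt character matrix of genotypes, rows aligned with `loci`, columns
#'   named by sample id.
#' @param groups named character vector mapping every sample id to a group
#'   label; exactly two non-empty groups are required. Labels are ordered
#'   alphabetically into (A, B).
#' @return an object of class `grouped_genotypes`.
#' @export
grouped_genotypes <- function(loci, gt, groups) {
  gt <- as.matrix(gt)
  samples <- colnames(gt)
  if (is.null(samples)) stop("grouped_genotypes: gt must have sample column names")
  if (nrow(gt) != nrow(loci)) {
    stop("grouped_genotypes: gt rows must align with loci rows")
  }
  if (!all(samples %in% names(groups))) {
    missing <- setdiff(samples, names(groups))
    stop("grouped_genotypes: samples missing from group map: ",
         paste(missing, collapse = ", "))
  }
  groups <- groups[samples]
  lv <- sort(unique(unname(groups)))
  if (length(lv) != 2L) {
    stop("grouped_genotypes: exactly two groups required, got ",
         length(lv))
  }
  rownames(gt) <- NULL
  rownames(loci) <- NULL
  structure(list(loci = loci, gt = gt, samples = samples, groups = groups,
                 group_levels = lv),
            class = "grouped_genotypes")
}

#' @export
print.grouped_genotypes <- function(x, ...) {
  tab <- table(x$groups)
  cat("grouped_genotypes:", nrow(x$loci), "InDel loci x", length(x$samples),
      "samples (", paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Load a grouped genotype matrix from a VCF and a groups file
#'
#' Reads a multi-sample VCF v4.2 (GT FORMAT field) with `vcfR`, retains InDel
#' records only (SNPs and symbolic/structural alleles are skipped with a
#' logged count) and decomposes multiallelic records into per-alt biallelic
#' loci: at a decomposed locus, alleles equal to the focal alt become allele 1,
#' reference alleles stay 0, and genotypes carrying any other alt are set to
#' missing.
#'
#' @param vcf_path path to the VCF file.
#' @param groups either a path to a two-column TSV (`sample_id`, `group`) or a
#'   data.frame with those columns; every VCF sample must appear exactly once.
#' @param quiet suppress the skipped-record message.
#' @return a [grouped_genotypes()] object.
#' @export
load_matrix <- function(vcf_path, groups, quiet = FALSE) {
  if (is.character(groups)) {
    groups <- read.table(groups, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "group") %in% names(groups))) {
    stop("load_matrix: groups table needs columns 'sample_id' and 'group'")
  }
  if (anyDuplicated(groups$sample_id)) {
    stop("load_matrix: duplicated sample ids in groups table")
  }
  group_map <- setNames(groups$group, groups$sample_id)

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  n_rec <- nrow(vcf@fix)
  samples <- colnames(vcf@gt)[-1L]
  if (length(samples) == 0L) stop("load_matrix: VCF has no sample columns")
  absent <- setdiff(samples, names(group_map))
  if (length(absent) > 0L) {
    stop("load_matrix: VCF samples absent from groups file: ",
         paste(absent, collapse = ", "))
  }

  if (n_rec == 0L) {
    loci <- data.frame(chrom = character(), pos = integer(), ref = character(),
                       alt = character(), indel_length_bp = integer(),
                       indel_type = character(), stringsAsFactors = FALSE)
    gt0 <- matrix(character(), nrow = 0L, ncol = length(samples),
                  dimnames = list(NULL, samples))
    return(grouped_genotypes(loci, gt0, group_map))
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  chrom <- vcf@fix[, "CHROM"]
  pos <- as.integer(vcf@fix[, "POS"])
  ref <- vcf@fix[, "REF"]
  alt_field <- vcf@fix[, "ALT"]

  loci <- list(); gts <- list()
  n_skipped <- 0L
  is_seq <- function(a) grepl("^[ACGTNacgtn]+$", a)
  for (r in seq_len(n_rec)) {
    alts <- strsplit(alt_field[r], ",", fixed = TRUE)[[1L]]
    alleles <- parse_gt(gt_raw[r, samples])
    emitted <- FALSE
    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (!is_seq(ref[r]) || !is_seq(alt) || nchar(alt) == nchar(ref[r])) next
      # recode to a biallelic locus on (ref, alt k); other alts -> missing
      a1 <- alleles[1L, ]; a2 <- alleles[2L, ]
      other <- (!is.na(a1) & !(a1 %in% c(0L, k))) |
               (!is.na(a2) & !(a2 %in% c(0L, k)))
      r1 <- ifelse(a1 == k, 1L, ifelse(a1 == 0L, 0L, NA_integer_))
      r2 <- ifelse(a2 == k, 1L, ifelse(a2 == 0L, 0L, NA_integer_))
      r1[other] <- NA_integer_; r2[other] <- NA_integer_
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = chrom[r], pos = pos[r], ref = ref[r], alt = alt,
        indel_length_bp = abs(nchar(alt) - nchar(ref[r])),
        indel_type = if (nchar(alt) > nchar(ref[r])) "insertion" else "deletion",
        stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- format_gt(r1, r2)
      emitted <- TRUE
    }
    if (!emitted) n_skipped <- n_skipped + 1L
  }
  if (!quiet && n_skipped > 0L) {
    message("load_matrix: skipped ", n_skipped,
            " non-InDel record(s) (SNPs or symbolic alleles)")
  }
  if (length(loci) == 0L) {
    loci_df <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          indel_length_bp = integer(),
                          indel_type = character(), stringsAsFactors = FALSE)
    gt_mat <- matrix(character(), nrow = 0L, ncol = length(samples),
                     dimnames = list(NULL, samples))
  } else {
    loci_df <- do.call(rbind, loci)
    gt_mat <- do.call(rbind, gts)
    colnames(gt_mat) <- samples
  }
  grouped_genotypes(loci_df, gt_mat, group_map)
}
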