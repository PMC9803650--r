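#' Classify one InDel locus as group-diagnostic or not
#'
#' Implements the fixed-difference condition used to extract species-specific
#' InDels: a locus is `diagnostic` when every non-missing group-A sample is
#' homozygous for one allele, every non-missing group-B sample is homozygous
#' for a *different* allele, and the number of missing genotypes in each group
#' does not exceed `max_missing`. "Heterozygous between the two groups" is
#' read as fixation for different alleles, so that an inter-group cross is
#' heterozygous — not that any individual is heterozygous. When missingness
#' exceeds the policy in either group (or a group has no called genotype) the
#' status is `indeterminate`; every other configuration is `non_diagnostic`.
#'
#' @param matrix a [grouped_genotypes()] object.
#' @param locus locus row index in `matrix$loci`.
#' @param max_missing maximum tolerated missing genotypes per group
#'   (default 0: the strictest reading of "homozygous within the groups").
#' @return a list of class `diagnostic_call`: `status`
#'   (diagnostic / non_diagnostic / indeterminate), `group_a_allele`,
#'   `group_b_allele` (allele indices, NA unless diagnostic), `n_missing_a`,
#'   `n_missing_b`.
#' @export
classify_locus <- function(matrix, locus, max_missing = 0L) {
  stopifnot(inherits(matrix, "grouped_genotypes"),
            locus >= 1L, locus <= nrow(matrix$loci))
  lv <- matrix$group_levels
  al <- parse_gt(matrix$gt[locus, ])
  grp <- unname(matrix$groups)

  group_state <- function(g) {
    idx <- which(grp == g)
    a1 <- al[1L, idx]; a2 <- al[2L, idx]
    miss <- is.na(a1) | is.na(a2)
    called1 <- a1[!miss]; called2 <- a2[!miss]
    hom <- length(called1) > 0L && all(called1 == called2) &&
      length(unique(called1)) == 1L
    list(n_missing = sum(miss), n_called = sum(!miss),
         uniform_hom = hom,
         allele = if (hom) called1[1L] else NA_integer_)
  }
  a <- group_state(lv[1L])
  b <- group_state(lv[2L])

  status <- if (a$n_missing > max_missing || b$n_missing > max_missing ||
                a$n_called == 0L || b$n_called == 0L) {
    "indeterminate"
  } else if (a$uniform_hom && b$uniform_hom && a$allele != b$allele) {
    "diagnostic"
  } else {
    "non_diagnostic"
  }
  structure(list(status = status,
                 group_a_allele = if (status == "diagnostic") a$allele else NA_integer_,
                 group_b_allele = if (status == "diagnostic") b$allele else NA_integer_,
                 n_missing_a = a$n_missing,
                 n_missing_b = b$n_missing),
            class = "diagnostic_call")
}

#' Scan a genotype matrix for group-diagnostic InDels
#'
#' Applies [classify_locus()] to every locus and returns the diagnostic ones,
#' sorted by InDel length descending — the longest first, since long InDels
#' give the most conveniently separable gel bands — with ties broken by
#' (chrom, pos) ascending.
#'
#' @inheritParams classify_locus
#' @return a data.frame of class `diagnostic_calls`: the locus columns plus
#'   `group_a_allele`, `group_b_allele`, `n_missing_a`, `n_missing_b` and
#'   `locus_index` (row in the input matrix).
#' @export
scan_diagnostic <- function(matrix, max_missing = 0L) {
  n <- nrow(matrix$loci)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classify_locus(matrix, i, max_missing)
    if (cl$status == "diagnostic") {
      rows[[i]] <- cbind(matrix$loci[i, , drop = FALSE],
                         data.frame(group_a_allele = cl$group_a_allele,
                                    group_b_allele = cl$group_b_allele,
                                    n_missing_a = cl$n_missing_a,
                                    n_missing_b = cl$n_missing_b,
                                    locus_index = i))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(matrix$loci[0, , drop = FALSE],
                 data.frame(group_a_allele = integer(),
                            group_b_allele = integer(),
                            n_missing_a = integer(), n_missing_b = integer(),
                            locus_index = integer()))
  }
  ord <- order(-out$indel_length_bp, out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_calls", "data.frame")
  out
}

#' Per-sample homozygosity summary
#'
#' Counts, for each sample over all loci, the sites homozygous for the
#' reference allele (`n_ref_homo`), homozygous for an alternate allele
#' (`n_alt_homo`), heterozygous (`n_het`) and missing (`n_missing`). When the
#' reference assembly belongs to one of the two groups, samples from the other
#' group show inflated alt-homozygote counts — the asymmetry this summary is
#' designed to expose. The four classes always sum to `n_total`.
#'
#' @param matrix a [grouped_genotypes()] object.
#' @return a data.frame with one row per sample: sample_id, group, n_ref_homo,
#'   n_alt_homo, n_het, n_missing, n_total.
#' @export
summarize_samples <- function(matrix) {
  n_loci <- nrow(matrix$loci)
  res <- lapply(matrix$samples, function(s) {
    al <- parse_gt(matrix$gt[, s])
    a1 <- al[1L, ]; a2 <- al[2L, ]
    miss <- is.na(a1) | is.na(a2)
    hom <- !miss & a1 == a2
    data.frame(sample_id = s, group = unname(matrix$groups[s]),
               n_ref_homo = sum(hom & a1 == 0L),
               n_alt_homo = sum(hom & a1 > 0L),
               n_het = sum(!miss & a1 != a2),
               n_missing = sum(miss),
               n_total = n_loci,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write diagnostic calls to a TSV file
#'
#' @param calls a `diagnostic_calls` data.frame from [scan_diagnostic()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_diagnostic_calls <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
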