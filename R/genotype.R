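#' Agarose gel resolvability model
#'
#' Resolvability is modeled as a single minimum band-size difference: two
#' amplicons closer than `min_resolvable_diff` co-migrate and are reported as
#' one band. The 20 bp default reflects what is comfortably separable on a 2%
#' agarose gel in the 150-400 bp range.
#'
#' @param agarose_percent gel concentration (informational).
#' @param min_resolvable_diff minimum separable size difference in bp (> 0).
#' @return an object of class `gel_model`.
#' @export
gel_model <- function(agarose_percent = 2, min_resolvable_diff = 20L) {
  stopifnot(min_resolvable_diff > 0)
  structure(list(agarose_percent = agarose_percent,
                 min_resolvable_diff = as.numeric(min_resolvable_diff)),
            class = "gel_model")
}

#' Predict the electrophoretic band pattern of one individual at one marker
#'
#' A codominant InDel marker produces one band per distinct allele: a
#' homozygote gives a single band at that allele's amplicon size, a
#' heterozygote gives both bands. Each band of a heterozygote is lost
#' independently with probability `dropout_rate` (allelic dropout). Bands
#' closer than the gel's minimum resolvable difference merge into one reported
#' band at their mean size, flagged via the `merged` field.
#'
#' @param marker a one-row `marker_candidates` data.frame (needs marker_id,
#'   amplicon_ref, amplicon_alt).
#' @param genotype a diploid genotype string over the marker's two alleles
#'   (`"0/0"`, `"0/1"`, `"1/1"`, or missing).
#' @param gel a [gel_model()].
#' @param dropout_rate per-band dropout probability in [0,1].
#' @param sample_id optional sample label carried through.
#' @return a list of class `band_pattern`: marker_id, sample_id, bands
#'   (sorted numeric vector of sizes, possibly empty), merged (logical),
#'   source = "predicted".
#' @export
predict_bands <- function(marker, genotype, gel = gel_model(),
                          dropout_rate = 0, sample_id = NA_character_) {
  stopifnot(dropout_rate >= 0, dropout_rate <= 1)
  sizes <- c(`0` = marker$amplicon_ref, `1` = marker$amplicon_alt)
  al <- parse_gt(genotype)[, 1L]
  merged <- FALSE
  if (anyNA(al)) {
    bands <- numeric(0)
  } else {
    if (any(!al %in% c(0L, 1L))) {
      stop("predict_bands: genotype references an allele the marker lacks")
    }
    if (al[1L] == al[2L]) {
      bands <- unname(sizes[as.character(al[1L])])
    } else {
      bands <- unname(sizes)
      kept <- runif(2L) >= dropout_rate
      bands <- bands[kept]
      if (length(bands) == 2L &&
          abs(bands[1L] - bands[2L]) < gel$min_resolvable_diff) {
        bands <- round(mean(bands))
        merged <- TRUE
      }
    }
  }
  structure(list(marker_id = marker$marker_id, sample_id = sample_id,
                 bands = sort(unique(bands)), merged = merged,
                 source = "predicted"),
            class = "band_pattern")
}

#' Call a genotype from an observed or predicted band pattern
#'
#' Bands are matched to the marker's two allele amplicon sizes within
#' `tolerance` bp. Two distinct matched alleles give `het`; a single matched
#' allele gives the corresponding homozygote call (`hom_a` for the alternate /
#' group-A allele, `hom_b` for the reference / group-B allele) unless the
#' pedigree expects a heterozygote, in which case the single band is flagged
#' `dropout_suspect` (allelic dropout or a null allele); no matched band gives
#' `fail`. A band within tolerance of both alleles makes the pattern
#' unresolvable and the call `fail`.
#'
#' @param marker a one-row `marker_candidates` data.frame.
#' @param pattern a `band_pattern` or a numeric vector of band sizes.
#' @param pedigree_expectation optional expected call (`"het"` for known F1
#'   offspring of fixed-difference parents).
#' @param tolerance band-size matching tolerance in bp (default 5).
#' @return a list of class `genotype_call`: marker_id, sample_id, call
#'   (hom_a / hom_b / het / dropout_suspect / fail), reason,
#'   expected_bands, observed_bands.
#' @export
call_genotype <- function(marker, pattern, pedigree_expectation = NULL,
                          tolerance = 5) {
  if (inherits(pattern, "band_pattern")) {
    bands <- pattern$bands
    sample_id <- pattern$sample_id
  } else {
    bands <- as.numeric(pattern)
    sample_id <- NA_character_
  }
  expected <- sort(c(marker$amplicon_ref, marker$amplicon_alt))
  match_b <- abs(bands - marker$amplicon_ref) <= tolerance
  match_a <- abs(bands - marker$amplicon_alt) <= tolerance

  mk <- function(call, reason = NA_character_) {
    structure(list(marker_id = marker$marker_id, sample_id = sample_id,
                   call = call, reason = reason,
                   expected_bands = expected, observed_bands = bands),
              class = "genotype_call")
  }
  if (length(bands) == 0L) return(mk("fail", "no bands"))
  if (any(match_a & match_b)) return(mk("fail", "unresolvable"))
  alleles <- unique(c(if (any(match_a)) "a", if (any(match_b)) "b"))
  if (length(alleles) == 0L) return(mk("fail", "no band matches an allele"))
  if (length(alleles) == 2L) return(mk("het"))
  single <- if (alleles == "a") "hom_a" else "hom_b"
  if (!is.null(pedigree_expectation) && identical(pedigree_expectation, "het")) {
    return(mk("dropout_suspect", "single band where pedigree expects two"))
  }
  mk(single)
}

#' Evaluate a marker panel over genotyped individuals
#'
#' Predicts band patterns for every (marker, individual) pair from the true
#' genotypes (with per-band dropout), calls genotypes back from the patterns,
#' and scores each marker against the individuals' known classes: parental
#' group A must call `hom_a`, parental group B `hom_b`, F1 hybrids `het`
#' (F1s carry a pedigree expectation of heterozygosity, so single bands there
#' surface as `dropout_suspect`). A marker is accepted only when every
#' individual is called correctly with no dropout suspects and no failures —
#' one bad individual rejects the marker, mirroring how a marker whose F1s
#' show single bands is discarded.
#'
#' @param markers a `marker_candidates` data.frame.
#' @param genotypes character matrix of true genotypes, rows indexed by marker
#'   locus (`markers$locus_index` order must match rows) and columns named by
#'   individual.
#' @param classes named character vector over individuals with values
#'   `"parental_A"`, `"parental_B"` or `"F1"`.
#' @param gel a [gel_model()].
#' @param dropout_rate per-band dropout probability applied to heterozygotes;
#'   may be a single value or a named vector per marker_id.
#' @param seed integer seed for the dropout draws.
#' @param tolerance band matching tolerance in bp.
#' @return a list of class `panel_report`: `per_marker` (marker_id, tier,
#'   counts of correct/miscall/dropout_suspect/fail, accepted, reason) and
#'   `calls` (long data.frame of all individual calls).
#' @export
evaluate_marker_panel <- function(markers, genotypes, classes,
                                  gel = gel_model(), dropout_rate = 0,
                                  seed = 1L, tolerance = 5) {
  individuals <- colnames(genotypes)
  if (is.null(individuals) || length(individuals) == 0L) {
    # nothing tested: empty report, no acceptance decisions
    return(structure(list(
      per_marker = data.frame(marker_id = character(), tier = character(),
                              n_tested = integer(), n_correct = integer(),
                              n_miscall = integer(),
                              n_dropout_suspect = integer(),
                              n_fail = integer(), accepted = logical(),
                              reason = character(), stringsAsFactors = FALSE),
      calls = data.frame(marker_id = character(), sample_id = character(),
                         class = character(), expected = character(),
                         call = character(), reason = character(),
                         n_bands = integer(), stringsAsFactors = FALSE)),
      class = "panel_report"))
  }
  stopifnot(all(individuals %in% names(classes)))
  if (nrow(markers) > 0L) {
    stopifnot(nrow(genotypes) == nrow(markers))
  }
  expected_call <- c(parental_A = "hom_a", parental_B = "hom_b", F1 = "het")

  with_seed(derive_seed(seed, 4L), {
    calls <- list()
    for (m in seq_len(nrow(markers))) {
      marker <- markers[m, ]
      dr <- if (length(dropout_rate) > 1L) {
        unname(dropout_rate[marker$marker_id])
      } else dropout_rate
      for (ind in individuals) {
        cls <- classes[[ind]]
        pat <- predict_bands(marker, genotypes[m, ind], gel = gel,
                             dropout_rate = dr, sample_id = ind)
        gcall <- call_genotype(marker, pat,
                               pedigree_expectation =
                                 if (cls == "F1") "het" else NULL,
                               tolerance = tolerance)
        calls[[length(calls) + 1L]] <- data.frame(
          marker_id = marker$marker_id, sample_id = ind, class = cls,
          expected = expected_call[[cls]], call = gcall$call,
          reason = gcall$reason %||% NA_character_,
          n_bands = length(pat$bands), stringsAsFactors = FALSE)
      }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
      data.frame(marker_id = character(), sample_id = character(),
                 class = character(), expected = character(),
                 call = character(), reason = character(),
                 n_bands = integer(), stringsAsFactors = FALSE)

    per_marker <- lapply(markers$marker_id, function(mid) {
      cc <- calls[calls$marker_id == mid, , drop = FALSE]
      n_correct <- sum(cc$call == cc$expected)
      n_dropout <- sum(cc$call == "dropout_suspect")
      n_fail <- sum(cc$call == "fail")
      n_miscall <- nrow(cc) - n_correct - n_dropout - n_fail
      accepted <- nrow(cc) > 0L && n_correct == nrow(cc)
      reason <- if (accepted) {
        NA_character_
      } else if (nrow(cc) == 0L) {
        "no individuals tested"
      } else if (n_dropout > 0L) {
        sprintf("%d dropout_suspect call(s) among F1s", n_dropout)
      } else if (n_fail > 0L) {
        sprintf("%d failed call(s)", n_fail)
      } else {
        sprintf("%d miscall(s)", n_miscall)
      }
      data.frame(marker_id = mid,
                 tier = markers$tier[markers$marker_id == mid],
                 n_tested = nrow(cc), n_correct = n_correct,
                 n_miscall = n_miscall, n_dropout_suspect = n_dropout,
                 n_fail = n_fail, accepted = accepted, reason = reason,
                 stringsAsFactors = FALSE)
    })
    per_marker <- if (length(per_marker)) do.call(rbind, per_marker) else
      data.frame(marker_id = character(), tier = character(),
                 n_tested = integer(), n_correct = integer(),
                 n_miscall = integer(), n_dropout_suspect = integer(),
                 n_fail = integer(), accepted = logical(),
                 reason = character(), stringsAsFactors = FALSE)
    structure(list(per_marker = per_marker, calls = calls),
              class = "panel_report")
  })
}

#' @export
print.panel_report <- function(x, ...) {
  n <- nrow(x$per_marker)
  cat("panel_report:", n, "marker(s),", sum(x$per_marker$accepted),
      "accepted\n")
  if (n > 0L) print(x$per_marker[, c("marker_id", "tier", "n_tested",
                                     "n_correct", "n_dropout_suspect",
                                     "n_fail", "accepted")])
  invisible(x)
}
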