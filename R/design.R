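#' Primer design constraints
#'
#' The constraint set used to design agarose-resolvable InDel markers:
#' amplicons of 150-400 bp (both allele templates must fit), primer melting
#' temperature 48-60 degrees C, primer GC content 40-60%, and only InDels
#' strictly longer than `min_indel_length` (default 20 bp) considered, so the
#' two allele bands separate visibly on a 2% gel.
#'
#' @param amplicon_min,amplicon_max allowed amplicon size range in bp.
#' @param tm_min,tm_max allowed primer melting temperature range, degrees C.
#' @param gc_min,gc_max allowed primer GC range, percent.
#' @param primer_len_min,primer_len_max primer length range in bp.
#' @param min_indel_length only loci with InDel length strictly greater than
#'   this are considered (bp).
#' @param tm_method melting-temperature method, see [melting_temperature()].
#' @return an object of class `primer_constraints`.
#' @export
primer_constraints <- function(amplicon_min = 150L, amplicon_max = 400L,
                               tm_min = 48, tm_max = 60,
                               gc_min = 40, gc_max = 60,
                               primer_len_min = 18L, primer_len_max = 27L,
                               min_indel_length = 20L,
                               tm_method = "nn") {
  stopifnot(amplicon_min < amplicon_max, tm_min < tm_max, gc_min < gc_max,
            primer_len_min >= 10L, primer_len_max >= primer_len_min)
  structure(list(amplicon_min = as.integer(amplicon_min),
                 amplicon_max = as.integer(amplicon_max),
                 tm_min = tm_min, tm_max = tm_max,
                 gc_min = gc_min, gc_max = gc_max,
                 primer_len_min = as.integer(primer_len_min),
                 primer_len_max = as.integer(primer_len_max),
                 min_indel_length = as.integer(min_indel_length),
                 tm_method = tm_method),
            class = "primer_constraints")
}

#' Assign a marker tier from InDel length
#'
#' Tiers partition InDel lengths into the mutually exclusive intervals
#' `>50`, `(40,50]`, `(34,40]` and `(20,34]` bp; longer InDels give more
#' easily separable bands.
#'
#' @param indel_length_bp integer vector of InDel lengths (> 20).
#' @return character vector of tiers: ">50", ">40", ">34", ">20".
#' @export
indel_tier <- function(indel_length_bp) {
  ifelse(indel_length_bp > 50L, ">50",
         ifelse(indel_length_bp > 40L, ">40",
                ifelse(indel_length_bp > 34L, ">34", ">20")))
}

#' Design PCR marker candidates for diagnostic InDel loci
#'
#' For each diagnostic locus longer than `min_indel_length`, searches all
#' primer placements on the reference template with the InDel strictly between
#' the two primer binding sites, both primers within the Tm/GC/length bounds,
#' and *both* allele amplicons (reference allele and alternate allele, which
#' differ by exactly the InDel length) within the amplicon size range. At most
#' one pair is emitted per locus: the pair whose reference amplicon is closest
#' to the midpoint of the size range, with ties broken by smaller amplicon,
#' then leftmost forward start, then leftmost reverse end, then shorter
#' primers (at a given binding position only the shortest valid primer is
#' considered, since all longer ones rank strictly worse). The selected pair
#' must additionally be unique within +/- 10 kb of
#' the locus (each primer matching exactly one site over both strands);
#' non-unique pairs are passed over for the next-best pair. Input order
#' (InDel length descending) is preserved. Loci where no placement satisfies
#' all constraints (e.g. too close to a contig edge) are skipped and reported
#' in the `skipped` attribute.
#'
#' @param calls a `diagnostic_calls` data.frame from [scan_diagnostic()].
#' @param reference a [Biostrings::DNAStringSet] (or `sim_reference`).
#' @param constraints a [primer_constraints()] object.
#' @param uniqueness_window half-width of the local specificity window, bp;
#'   set to 0 to disable the local uniqueness screen.
#' @param max_uniqueness_tries how many top-ranked pairs to screen for local
#'   uniqueness before skipping the locus.
#' @return data.frame of class `marker_candidates`, one row per designed
#'   marker: marker_id, locus fields, tier, primer sequences/coordinates,
#'   tm_f, tm_r, gc_f, gc_r, amplicon_ref, amplicon_alt.
#' @export
design_candidates <- function(calls, reference,
                              constraints = primer_constraints(),
                              uniqueness_window = 10000L,
                              max_uniqueness_tries = 25L) {
  if (inherits(reference, "sim_reference")) reference <- reference$sequences
  stopifnot(inherits(constraints, "primer_constraints"))
  seq_chr <- setNames(as.character(reference), names(reference))

  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    if (call$indel_length_bp <= constraints$min_indel_length) next
    res <- design_one_locus(call, seq_chr[[call$chrom]], constraints,
                            uniqueness_window, max_uniqueness_tries)
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        chrom = call$chrom, pos = call$pos, reason = res,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- cbind(call, res)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(calls[0, , drop = FALSE], empty_design_df())
  }
  out$marker_id <- sprintf("HM%d", seq_len(nrow(out)))
  out$tier <- indel_tier(out$indel_length_bp)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  class(out) <- c("marker_candidates", "data.frame")
  out
}

empty_design_df <- function() {
  data.frame(fwd_seq = character(), fwd_start = integer(), fwd_end = integer(),
             rev_seq = character(), rev_start = integer(), rev_end = integer(),
             tm_f = numeric(), tm_r = numeric(),
             gc_f = numeric(), gc_r = numeric(),
             amplicon_ref = integer(), amplicon_alt = integer(),
             stringsAsFactors = FALSE)
}

# Search for the best primer pair at one locus; returns a one-row data.frame
# or a character reason when no feasible pair exists.
design_one_locus <- function(call, chrom_seq, cn, uniq_win, max_tries) {
  chrom_len <- nchar(chrom_seq)
  pos <- call$pos
  indel_last <- pos + nchar(call$ref) - 1L # last reference base of REF field
  delta <- nchar(call$alt) - nchar(call$ref)

  # the reference amplicon must satisfy both allele size constraints
  lo <- max(cn$amplicon_min, cn$amplicon_min - delta)
  hi <- min(cn$amplicon_max, cn$amplicon_max - delta)
  if (lo > hi) return("no amplicon size satisfies both alleles")

  win_start <- max(1L, pos - cn$amplicon_max)
  win_end <- min(chrom_len, indel_last + cn$amplicon_max)

  if (pos - cn$primer_len_min < win_start ||
      indel_last + cn$primer_len_min > win_end) {
    return("locus too close to contig edge")
  }

  lens <- cn$primer_len_min:cn$primer_len_max
  # forward primers: plus strand, ending at or before the anchor base
  f_start <- seq(win_start, pos - cn$primer_len_min)
  fwd <- expand.grid(start = f_start, len = lens, KEEP.OUT.ATTRS = FALSE)
  fwd$end <- fwd$start + fwd$len - 1L
  fwd <- fwd[fwd$end <= pos, , drop = FALSE]
  # reverse primers: minus strand, binding entirely after the REF span
  r_end <- seq(indel_last + cn$primer_len_min,
               min(win_end, indel_last + cn$amplicon_max))
  rev <- expand.grid(end = r_end, len = lens, KEEP.OUT.ATTRS = FALSE)
  rev$start <- rev$end - rev$len + 1L
  rev <- rev[rev$start > indel_last & rev$end <= win_end, , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    return("locus too close to contig edge")
  }

  filter_primers <- function(df, reverse) {
    seqs <- substring(chrom_seq, df$start, df$end)
    if (reverse) seqs <- revcomp(seqs)
    gc <- gc_content(seqs)
    keep <- gc >= cn$gc_min & gc <= cn$gc_max
    df <- df[keep, , drop = FALSE]; seqs <- seqs[keep]; gc <- gc[keep]
    if (nrow(df) == 0L) return(NULL)
    tm <- melting_temperature(seqs, method = cn$tm_method)
    keep <- tm >= cn$tm_min & tm <= cn$tm_max
    if (!any(keep)) return(NULL)
    cbind(df[keep, , drop = FALSE],
          data.frame(seq = seqs[keep], gc = gc[keep], tm = tm[keep],
                     stringsAsFactors = FALSE))
  }
  fwd <- filter_primers(fwd, reverse = FALSE)
  rev <- filter_primers(rev, reverse = TRUE)
  if (is.null(fwd) || is.null(rev)) {
    return("no primer satisfies Tm/GC constraints")
  }
  # the tie-break order prefers the shortest valid primer at a given binding
  # position, so collapse each position to that primer before pairing
  fwd <- fwd[order(fwd$start, fwd$len), , drop = FALSE]
  fwd <- fwd[!duplicated(fwd$start), , drop = FALSE]
  rev <- rev[order(rev$end, rev$len), , drop = FALSE]
  rev <- rev[!duplicated(rev$end), , drop = FALSE]

  # pair up under the amplicon size bounds (vectorized over the cross product)
  amp <- outer(rev$end, fwd$start, function(e, s) e - s + 1L)
  ok <- which(amp >= lo & amp <= hi, arr.ind = TRUE)
  if (nrow(ok) == 0L) return("no pair satisfies amplicon size bounds")
  ri <- ok[, 1L]; fi <- ok[, 2L]
  amplicon_ref <- amp[ok]

  mid <- (cn$amplicon_min + cn$amplicon_max) / 2
  ord <- order(abs(amplicon_ref - mid), amplicon_ref,
               fwd$start[fi], rev$end[ri], fwd$len[fi], rev$len[ri])
  ord <- ord[seq_len(min(length(ord), max_tries))]
  fi <- fi[ord]; ri <- ri[ord]
  pairs <- data.frame(
    start_f = fwd$start[fi], end_f = fwd$end[fi], len_f = fwd$len[fi],
    seq_f = fwd$seq[fi], gc_f = fwd$gc[fi], tm_f = fwd$tm[fi],
    start_r = rev$start[ri], end_r = rev$end[ri], len_r = rev$len[ri],
    seq_r = rev$seq[ri], gc_r = rev$gc[ri], tm_r = rev$tm[ri],
    amplicon_ref = amplicon_ref[ord], stringsAsFactors = FALSE)

  if (uniq_win > 0L) {
    uw_start <- max(1L, pos - uniq_win)
    uw_end <- min(chrom_len, pos + uniq_win)
    uniq_region <- Biostrings::DNAString(substring(chrom_seq, uw_start, uw_end))
    locally_unique <- function(p) {
      n <- Biostrings::countPattern(Biostrings::DNAString(p), uniq_region) +
        Biostrings::countPattern(
          Biostrings::reverseComplement(Biostrings::DNAString(p)), uniq_region)
      n == 1L
    }
  } else {
    locally_unique <- function(p) TRUE
  }
  for (k in seq_len(min(nrow(pairs), max_tries))) {
    p <- pairs[k, ]
    if (locally_unique(p$seq_f) && locally_unique(p$seq_r)) {
      return(data.frame(
        fwd_seq = p$seq_f, fwd_start = p$start_f, fwd_end = p$end_f,
        rev_seq = p$seq_r, rev_start = p$start_r, rev_end = p$end_r,
        tm_f = p$tm_f, tm_r = p$tm_r, gc_f = p$gc_f, gc_r = p$gc_r,
        amplicon_ref = p$amplicon_ref,
        amplicon_alt = p$amplicon_ref + delta,
        stringsAsFactors = FALSE))
    }
  }
  "no locally unique primer pair"
}

#' Count designed markers per tier
#'
#' @param candidates a `marker_candidates` data.frame.
#' @return data.frame with columns tier and count over the four tiers
#'   (zero counts included); counts sum to `nrow(candidates)`.
#' @export
tier_counts <- function(candidates) {
  tiers <- c(">50", ">40", ">34", ">20")
  counts <- table(factor(candidates$tier, levels = tiers))
  data.frame(tier = tiers, count = as.integer(counts),
             stringsAsFactors = FALSE)
}
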