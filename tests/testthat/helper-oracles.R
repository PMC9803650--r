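# Independent brute-force oracles used to cross-check the implementation.

# --- diagnostic predicate oracle -------------------------------------------
# Direct restatement of the fixed-difference condition on genotype strings,
# evaluated without any of the package's parsing helpers.
oracle_classify <- function(gt_a, gt_b, max_missing = 0L) {
  split_gt <- function(g) strsplit(g, "[/|]")
  is_missing <- function(g) {
    p <- split_gt(g)[[1]]
    length(p) != 2 || any(p == ".")
  }
  miss_a <- vapply(gt_a, is_missing, logical(1))
  miss_b <- vapply(gt_b, is_missing, logical(1))
  if (sum(miss_a) > max_missing || sum(miss_b) > max_missing ||
      all(miss_a) || all(miss_b)) {
    return("indeterminate")
  }
  hom_allele <- function(g) {
    p <- split_gt(g)[[1]]
    if (p[1] == p[2]) p[1] else NA_character_
  }
  al_a <- vapply(gt_a[!miss_a], hom_allele, character(1))
  al_b <- vapply(gt_b[!miss_b], hom_allele, character(1))
  if (!anyNA(al_a) && !anyNA(al_b) &&
      length(unique(al_a)) == 1 && length(unique(al_b)) == 1 &&
      unique(al_a) != unique(al_b)) {
    "diagnostic"
  } else {
    "non_diagnostic"
  }
}

# Build a one-locus grouped_genotypes object from two genotype vectors.
toy_matrix <- function(gt_a, gt_b, ref = "ATTTTT", alt = "A") {
  samples <- c(sprintf("A%d", seq_along(gt_a)),
               sprintf("B%d", seq_along(gt_b)))
  gt <- matrix(c(gt_a, gt_b), nrow = 1,
               dimnames = list(NULL, samples))
  loci <- data.frame(chrom = "chr1", pos = 1000L, ref = ref, alt = alt,
                     indel_length_bp = abs(nchar(alt) - nchar(ref)),
                     indel_type = if (nchar(alt) > nchar(ref)) "insertion"
                                  else "deletion",
                     stringsAsFactors = FALSE)
  grouped_genotypes(loci, gt,
                    setNames(rep(c("A", "B"), c(length(gt_a), length(gt_b))),
                             samples))
}

# --- annotation oracle ------------------------------------------------------
# Paints a category over every base of each chromosome, lowest precedence
# first, so the highest-precedence (most specific) category survives at each
# position. Completely set-based, unlike the per-transcript arithmetic in the
# package.
oracle_annotation_map <- function(genes, chrom, chrom_len,
                                  upstream = 5000L, downstream = 5000L) {
  map <- rep("intergenic", chrom_len)
  paint <- function(from, to, cat) {
    from <- max(1L, from); to <- min(chrom_len, to)
    if (from <= to) map[from:to] <<- cat
  }
  tx <- genes$transcripts[genes$transcripts$chrom == chrom, , drop = FALSE]
  layers <- c("downstream", "upstream", "transcript", "intron", "exon",
              "utr3", "utr5", "splice_site_region", "splice_site_acceptor",
              "splice_site_donor")
  for (layer in layers) {
    for (r in seq_len(nrow(tx))) {
      t <- tx[r, ]
      plus <- t$strand == "+"
      ex <- genes$exons[genes$exons$transcript_id == t$transcript_id, ,
                        drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      cds <- genes$cds[genes$cds$transcript_id == t$transcript_id, ,
                       drop = FALSE]
      introns <- if (nrow(ex) > 1) {
        data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
      } else data.frame(start = integer(), end = integer())
      switch(layer,
        downstream = if (plus) paint(t$end + 1L, t$end + downstream, layer)
                     else paint(t$start - downstream, t$start - 1L, layer),
        upstream = if (plus) paint(t$start - upstream, t$start - 1L, layer)
                   else paint(t$end + 1L, t$end + upstream, layer),
        transcript = if (nrow(ex) == 0) paint(t$start, t$end, layer),
        intron = for (k in seq_len(nrow(introns))) {
          paint(introns$start[k], introns$end[k], layer)
        },
        exon = for (k in seq_len(nrow(ex))) paint(ex$start[k], ex$end[k], layer),
        utr3 = if (nrow(cds) > 0) {
          for (k in seq_len(nrow(ex))) {
            lo <- ex$start[k]; hi <- ex$end[k]
            if (plus) paint(max(lo, max(cds$end) + 1L), hi, layer)
            else paint(lo, min(hi, min(cds$start) - 1L), layer)
          }
        },
        utr5 = if (nrow(cds) > 0) {
          for (k in seq_len(nrow(ex))) {
            lo <- ex$start[k]; hi <- ex$end[k]
            if (plus) paint(lo, min(hi, min(cds$start) - 1L), layer)
            else paint(max(lo, max(cds$end) + 1L), hi, layer)
          }
        },
        splice_site_region = {
          for (k in seq_len(nrow(introns))) {
            s <- introns$start[k]; e <- introns$end[k]
            paint(s + 2L, min(s + 7L, e), layer)
            paint(max(e - 7L, s), e - 2L, layer)
          }
          n <- nrow(ex)
          for (k in seq_len(n)) {
            if (k < n) paint(ex$end[k] - 2L, ex$end[k], layer)
            if (k > 1) paint(ex$start[k], ex$start[k] + 2L, layer)
          }
        },
        splice_site_acceptor = for (k in seq_len(nrow(introns))) {
          s <- introns$start[k]; e <- introns$end[k]
          if (plus) paint(e - 1L, e, layer) else paint(s, s + 1L, layer)
        },
        splice_site_donor = for (k in seq_len(nrow(introns))) {
          s <- introns$start[k]; e <- introns$end[k]
          if (plus) paint(s, s + 1L, layer) else paint(e - 1L, e, layer)
        }
      )
    }
  }
  map
}

# --- primer design oracle ---------------------------------------------------
# Plain nested-loop enumeration of every primer pair, applying each constraint
# literally and picking the best by the documented tie-break order.
oracle_design <- function(call, chrom_seq, cn) {
  chrom_len <- nchar(chrom_seq)
  pos <- call$pos
  indel_last <- pos + nchar(call$ref) - 1L
  delta <- nchar(call$alt) - nchar(call$ref)
  win_start <- max(1L, pos - cn$amplicon_max)
  win_end <- min(chrom_len, indel_last + cn$amplicon_max)
  ok_primer <- function(p) {
    gc <- 100 * lengths(regmatches(p, gregexpr("[GC]", p))) / nchar(p)
    if (gc < cn$gc_min || gc > cn$gc_max) return(FALSE)
    tm <- melting_temperature(p, method = cn$tm_method)
    tm >= cn$tm_min && tm <= cn$tm_max
  }
  best <- NULL
  mid <- (cn$amplicon_min + cn$amplicon_max) / 2
  for (fs in win_start:(pos - cn$primer_len_min)) {
    for (fl in cn$primer_len_min:cn$primer_len_max) {
      fe <- fs + fl - 1L
      if (fe > pos) next
      fseq <- substr(chrom_seq, fs, fe)
      if (!ok_primer(fseq)) next
      for (re in (indel_last + cn$primer_len_min):win_end) {
        amp <- re - fs + 1L
        if (amp < cn$amplicon_min || amp > cn$amplicon_max) next
        if (amp + delta < cn$amplicon_min || amp + delta > cn$amplicon_max) next
        for (rl in cn$primer_len_min:cn$primer_len_max) {
          rs <- re - rl + 1L
          if (rs <= indel_last) next
          rseq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(substr(chrom_seq, rs, re))))
          if (!ok_primer(rseq)) next
          key <- c(abs(amp - mid), amp, fs, re, fl, rl)
          if (is.null(best) ||
              isTRUE(order_lt(key, best$key))) {
            best <- list(key = key, fwd_seq = fseq, rev_seq = rseq,
                         fwd_start = fs, fwd_end = fe,
                         rev_start = rs, rev_end = re,
                         amplicon_ref = amp, amplicon_alt = amp + delta)
          }
          break # shortest valid reverse primer at this end position wins
        }
      }
      break # shortest valid forward primer at this start position wins
    }
  }
  best
}

order_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}
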