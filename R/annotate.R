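ANNOTATION_CATEGORIES <- c("splice_site_donor", "splice_site_acceptor",
                           "splice_site_region", "utr5", "utr3", "exon",
                           "intron", "transcript", "upstream", "downstream",
                           "intergenic", "none")

#' Annotate InDel loci by genomic context
#'
#' Assigns each InDel (by its VCF anchor position) to one of twelve genomic
#' context categories against a transcript annotation, following snpEff-style
#' conventions: splice donor/acceptor are the first/last 2 bp of an intron in
#' transcription direction; the splice-site region covers 3-8 bp into the
#' intron and the 3 exonic bp flanking an internal junction; 5'/3' UTRs are
#' exonic regions outside the CDS, oriented by strand; `exon` is coding exon
#' (or any exon when the transcript has no CDS); `transcript` is inside the
#' transcript span when no exon structure is available; upstream/downstream
#' are windows beyond the transcript ends; everything else on an annotated
#' chromosome is `intergenic`. When a locus overlaps several transcripts, the
#' most specific (highest-precedence) category wins:
#' donor/acceptor > splice region > UTR > exon > intron > transcript >
#' upstream > downstream > intergenic. A locus on a chromosome absent from the
#' annotation is `none` in lenient mode and an error in strict mode.
#'
#' @param loci data.frame with at least `chrom` and `pos` columns.
#' @param genes a [gene_models()] object.
#' @param upstream,downstream window sizes in bp (default 5000).
#' @param splice_site_bp donor/acceptor width in bp inside the intron.
#' @param splice_region_intron integer range (bp into the intron) counted as
#'   splice-site region.
#' @param splice_region_exon exonic bp adjacent to an internal junction
#'   counted as splice-site region.
#' @param strict error on unknown chromosome instead of category `none`.
#' @return the input data.frame with a `category` column appended.
#' @export
annotate_indels <- function(loci, genes, upstream = 5000L, downstream = 5000L,
                            splice_site_bp = 2L,
                            splice_region_intron = c(3L, 8L),
                            splice_region_exon = 3L,
                            strict = FALSE) {
  stopifnot(inherits(genes, "gene_models"))
  tx <- genes$transcripts
  known_chroms <- unique(tx$chrom)
  win <- max(upstream, downstream)

  # shortlist transcripts within the window of each position
  if (nrow(tx) > 0L && nrow(loci) > 0L) {
    tx_gr <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(pmax(1L, tx$start - win), tx$end + win))
    pos_gr <- GenomicRanges::GRanges(loci$chrom,
                                     IRanges::IRanges(loci$pos, loci$pos))
    # chromosomes absent from the annotation are resolved below ("none"),
    # so the seqlevel mismatch warning carries no information here
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(pos_gr, tx_gr, ignore.strand = TRUE))
    hit_list <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  } else {
    hit_list <- list()
  }

  categories <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]; pos <- loci$pos[i]
    if (!(chrom %in% known_chroms)) {
      if (strict) {
        stop("annotate_indels: chromosome '", chrom,
             "' absent from gene models (strict mode)")
      }
      categories[i] <- "none"
      next
    }
    cand <- hit_list[[as.character(i)]]
    cats <- vapply(cand, function(j) {
      classify_against_transcript(pos, tx[j, ], genes, upstream, downstream,
                                  splice_site_bp, splice_region_intron,
                                  splice_region_exon)
    }, character(1))
    cats <- cats[!is.na(cats)]
    categories[i] <- if (length(cats) == 0L) {
      "intergenic"
    } else {
      cats[which.min(match(cats, ANNOTATION_CATEGORIES))]
    }
  }
  loci$category <- categories
  loci
}

# Category of one position against one transcript (NA when unrelated).
classify_against_transcript <- function(pos, t, genes, upstream, downstream,
                                        ss_bp, sr_intron, sr_exon) {
  plus <- t$strand == "+"
  if (pos >= t$start && pos <= t$end) {
    ex <- genes$exons[genes$exons$transcript_id == t$transcript_id, ,
                      drop = FALSE]
    if (nrow(ex) == 0L) return("transcript")
    ex <- ex[order(ex$start), , drop = FALSE]
    in_exon <- which(pos >= ex$start & pos <= ex$end)
    if (length(in_exon) > 0L) {
      j <- in_exon[1L]
      # exonic bp adjacent to an *internal* junction
      near_right <- j < nrow(ex) && pos > ex$end[j] - sr_exon
      near_left <- j > 1L && pos < ex$start[j] + sr_exon
      if (near_right || near_left) return("splice_site_region")
      cds <- genes$cds[genes$cds$transcript_id == t$transcript_id, ,
                       drop = FALSE]
      if (nrow(cds) == 0L) return("exon")
      if (any(pos >= cds$start & pos <= cds$end)) return("exon")
      if (pos < min(cds$start)) return(if (plus) "utr5" else "utr3")
      if (pos > max(cds$end)) return(if (plus) "utr3" else "utr5")
      return("exon") # between CDS spans but exonic: coding context
    }
    # inside the span but outside all exons and introns (malformed models
    # where the transcript span exceeds the exon span): plain transcript
    if (pos < ex$start[1L] || pos > ex$end[nrow(ex)]) return("transcript")
    # intronic: locate the flanking intron
    k <- max(which(ex$end < pos))
    int_start <- ex$end[k] + 1L
    int_end <- ex$start[k + 1L] - 1L
    off5 <- if (plus) pos - int_start + 1L else int_end - pos + 1L
    off3 <- if (plus) int_end - pos + 1L else pos - int_start + 1L
    if (off5 <= ss_bp) return("splice_site_donor")
    if (off3 <= ss_bp) return("splice_site_acceptor")
    if ((off5 >= sr_intron[1L] && off5 <= sr_intron[2L]) ||
        (off3 >= sr_intron[1L] && off3 <= sr_intron[2L])) {
      return("splice_site_region")
    }
    return("intron")
  }
  up_lo <- if (plus) t$start - upstream else t$end + 1L
  up_hi <- if (plus) t$start - 1L else t$end + upstream
  if (pos >= up_lo && pos <= up_hi) return("upstream")
  dn_lo <- if (plus) t$end + 1L else t$start - downstream
  dn_hi <- if (plus) t$end + downstream else t$start - 1L
  if (pos >= dn_lo && pos <= dn_hi) return("downstream")
  NA_character_
}

#' Summarize annotation categories
#'
#' Tabulates category counts and percentages over all twelve categories
#' (zero-count categories included). Percentages are rounded to two decimals
#' and sum to 100 within 0.01; counts sum to the number of input loci.
#'
#' @param results a data.frame with a `category` column, as returned by
#'   [annotate_indels()].
#' @return data.frame with columns category, count, percentage (empty for
#'   empty input).
#' @export
summarize_categories <- function(results) {
  if (nrow(results) == 0L) {
    return(data.frame(category = character(), count = integer(),
                      percentage = numeric()))
  }
  counts <- table(factor(results$category, levels = ANNOTATION_CATEGORIES))
  data.frame(category = names(counts),
             count = as.integer(counts),
             percentage = round(100 * as.integer(counts) / nrow(results), 2),
             stringsAsFactors = FALSE)
}
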