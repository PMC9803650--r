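#' Gene model container
#'
#' A light container for transcript-level gene structure: one row per
#' transcript with span and strand, plus exon and CDS spans. Exons must be
#' non-overlapping, ordered and contained in the transcript span; CDS spans
#' must fall inside exons.
#'
#' @param transcripts data.frame with columns gene_id, transcript_id, chrom,
#'   strand, start, end.
#' @param exons data.frame with columns transcript_id, chrom, start, end.
#' @param cds data.frame with the same columns as `exons` (may be empty).
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(transcripts, exons, cds = empty_span_df()) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand",
                  "start", "end") %in% names(transcripts)),
            all(c("transcript_id", "chrom", "start", "end") %in% names(exons)))
  if (nrow(transcripts) > 0L) {
    stopifnot(all(transcripts$strand %in% c("+", "-")),
              all(transcripts$start <= transcripts$end))
    for (tid in unique(exons$transcript_id)) {
      e <- exons[exons$transcript_id == tid, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)])) {
        stop("gene_models: overlapping exons in ", tid)
      }
      span <- transcripts[transcripts$transcript_id == tid, ]
      if (any(e$start < span$start) || any(e$end > span$end)) {
        stop("gene_models: exon outside transcript span in ", tid)
      }
    }
  }
  structure(list(transcripts = transcripts,
                 exons = exons[order(exons$transcript_id, exons$start), ,
                               drop = FALSE],
                 cds = cds[order(cds$transcript_id, cds$start), ,
                           drop = FALSE]),
            class = "gene_models")
}

empty_tx_df <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

empty_span_df <- function() {
  data.frame(transcript_id = character(), chrom = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS features via `rtracklayer` and assembles them
#' into a [gene_models()] object. Transcripts are taken from mRNA features (or
#' `transcript` features); exons and CDS are attached through their `Parent`
#' attribute.
#'
#' @param path path to a GFF3 file.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(S4Vectors::mcols(gr)$type)
  ids <- as.character(S4Vectors::mcols(gr)$ID)
  parents <- S4Vectors::mcols(gr)$Parent
  parent1 <- vapply(as.list(parents), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))

  is_tx <- type %in% c("mRNA", "transcript")
  tx <- data.frame(
    gene_id = ifelse(is.na(parent1[is_tx]), ids[is_tx], parent1[is_tx]),
    transcript_id = ids[is_tx],
    chrom = as.character(GenomicRanges::seqnames(gr)[is_tx]),
    strand = as.character(GenomicRanges::strand(gr)[is_tx]),
    start = GenomicRanges::start(gr)[is_tx],
    end = GenomicRanges::end(gr)[is_tx],
    stringsAsFactors = FALSE
  )
  span_df <- function(sel) {
    data.frame(transcript_id = parent1[sel],
               chrom = as.character(GenomicRanges::seqnames(gr)[sel]),
               start = GenomicRanges::start(gr)[sel],
               end = GenomicRanges::end(gr)[sel],
               stringsAsFactors = FALSE)
  }
  gene_models(tx, span_df(type == "exon"), span_df(type == "CDS"))
}
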