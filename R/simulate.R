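#' Simulate a toy reference genome with gene models
#'
#' Draws random chromosome sequences (uniform base composition, GC close to
#' 0.5) and places non-overlapping gene models (gene -> mRNA -> exons + CDS,
#' both strands) at the configured density. Each gene gets a slot of equal
#' size along the chromosome and is placed randomly within it, which
#' guarantees non-overlap and raises a sizing error when the chromosome cannot
#' host the requested genes.
#'
#' @param config a [simulation_config()].
#' @return an object of class `sim_reference`: a list with `sequences`
#'   (a [Biostrings::DNAStringSet]), `genes` (a `gene_models` object) and the
#'   config used.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 1L), {
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
      rand_dna(config$chrom_length)
    }, character(1)))
    names(seqs) <- chroms

    n_genes_per_chrom <- round(config$gene_density * config$chrom_length / 1e6)
    tx <- list(); ex <- list(); cd <- list()
    gene_counter <- 0L
    min_exon <- 50L; min_intron <- 60L
    for (ch in chroms) {
      n_genes <- n_genes_per_chrom
      if (n_genes == 0L) next
      slot <- config$chrom_length %/% n_genes
      max_gene_len <- min(8000L, slot - 200L)
      if (max_gene_len < 1000L) {
        stop("simulate_reference: chrom_length too small to host ",
             n_genes, " genes per chromosome (slot ", slot, " bp)")
      }
      for (g in seq_len(n_genes)) {
        gene_counter <- gene_counter + 1L
        gid <- sprintf("gene%04d", gene_counter)
        tid <- paste0(gid, ".t1")
        glen <- sample(2000L:max_gene_len, 1L)
        slot_start <- (g - 1L) * slot + 1L
        gstart <- slot_start + sample.int(slot - glen - 100L, 1L)
        gend <- gstart + glen - 1L
        strand <- sample(c("+", "-"), 1L)

        n_exons <- sample(2:6, 1L)
        k <- 2L * n_exons - 1L
        mins <- ifelse(seq_len(k) %% 2L == 1L, min_exon, min_intron)
        spare <- glen - sum(mins)
        w <- runif(k)
        extra <- floor(w / sum(w) * spare)
        extra[k] <- spare - sum(extra[-k])
        seg_len <- mins + extra
        seg_end <- gstart - 1L + cumsum(seg_len)
        seg_start <- c(gstart, seg_end[-k] + 1L)
        exon_idx <- which(seq_len(k) %% 2L == 1L)
        exon_start <- seg_start[exon_idx]
        exon_end <- seg_end[exon_idx]

        # CDS placed inside the exonic (transcript) coordinate space, leaving
        # UTR on both sides.
        exlens <- exon_end - exon_start + 1L
        tx_len <- sum(exlens)
        cds_from <- sample(10:max(10L, floor(0.3 * tx_len)), 1L)
        cds_to <- sample(min(tx_len - 10L, ceiling(0.7 * tx_len)):(tx_len - 10L), 1L)
        cum <- cumsum(exlens)
        tx2g <- function(p) {
          i <- which(p <= cum)[1L]
          exon_start[i] + (p - c(0L, cum)[i]) - 1L
        }
        cds_g1 <- tx2g(cds_from); cds_g2 <- tx2g(cds_to)
        cds_spans <- data.frame(
          start = pmax(exon_start, cds_g1),
          end = pmin(exon_end, cds_g2)
        )
        cds_spans <- cds_spans[cds_spans$start <= cds_spans$end, , drop = FALSE]

        tx[[tid]] <- data.frame(gene_id = gid, transcript_id = tid, chrom = ch,
                                strand = strand, start = gstart, end = gend,
                                stringsAsFactors = FALSE)
        ex[[tid]] <- data.frame(transcript_id = tid, chrom = ch,
                                start = exon_start, end = exon_end,
                                stringsAsFactors = FALSE)
        cd[[tid]] <- data.frame(transcript_id = tid, chrom = ch,
                                start = cds_spans$start, end = cds_spans$end,
                                stringsAsFactors = FALSE)
      }
    }
    genes <- gene_models(
      transcripts = do.call(rbind, tx) %||% empty_tx_df(),
      exons = do.call(rbind, ex) %||% empty_span_df(),
      cds = do.call(rbind, cd) %||% empty_span_df()
    )
    structure(list(sequences = seqs, genes = genes, config = config),
              class = "sim_reference")
  })
}

#' Plant diagnostic and polymorphic InDels into a simulated reference
#'
#' Plants three classes of InDel variants at positions separated by at least
#' `variant_spacing` bp: `diagnostic` sites where every group-A sample is
#' homozygous for the alternate allele and every group-B sample homozygous for
#' the reference allele (the reference sequence carries the group-B allele,
#' mirroring a reference assembly that belongs to group B);
#' `shared_polymorphic` sites segregating within both groups; and
#' `private_polymorphic` sites segregating within exactly one group. Genotypes
#' are then masked to missing (`./.`) independently at `missing_rate`.
#'
#' @param reference a `sim_reference` from [simulate_reference()].
#' @param config the same [simulation_config()] (defaults to the one stored in
#'   `reference`).
#' @return a list with `matrix` (a [grouped_genotypes()] object) and `truth`
#'   (the truth table `data.frame` with one row per planted variant: chrom,
#'   pos, ref, alt, class, group_a_allele, group_b_allele, indel_length_bp).
#' @export
plant_variants <- function(reference, config = reference$config) {
  stopifnot(inherits(reference, "sim_reference"))
  with_seed(derive_seed(config$seed, 2L), {
    n_total <- config$n_diagnostic + config$n_shared_polymorphic +
      config$n_private_polymorphic
    chroms <- names(reference$sequences)
    step <- config$variant_spacing + config$indel_max_bp + 50L
    pool <- do.call(rbind, lapply(chroms, function(ch) {
      lo <- config$edge_margin
      hi <- config$chrom_length - config$edge_margin - config$indel_max_bp - 1L
      base <- seq(lo, hi, by = step)
      data.frame(chrom = ch,
                 pos = base + sample.int(40L, length(base), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    if (nrow(pool) < n_total) {
      stop("plant_variants: requested ", n_total, " variants but only ",
           nrow(pool), " positions available at >= ", config$variant_spacing,
           " bp spacing; increase chrom_length or n_chromosomes")
    }
    sel <- pool[sort(sample.int(nrow(pool), n_total)), , drop = FALSE]
    classes <- sample(rep(c("diagnostic", "shared_polymorphic",
                            "private_polymorphic"),
                          c(config$n_diagnostic, config$n_shared_polymorphic,
                            config$n_private_polymorphic)))

    samples <- c(sprintf("A%d", seq_len(config$n_group_a)),
                 sprintf("B%d", seq_len(config$n_group_b)))
    groups <- setNames(rep(c("A", "B"), c(config$n_group_a, config$n_group_b)),
                       samples)
    n_s <- length(samples)

    seq_chr <- setNames(as.character(reference$sequences), chroms)
    loci <- vector("list", n_total)
    gt <- matrix("0/0", nrow = n_total, ncol = n_s,
                 dimnames = list(NULL, samples))
    truth <- vector("list", n_total)

    segregating_genos <- function(n) {
      # genotypes for one group at a biallelic site, forced to segregate
      repeat {
        g <- sample(c("0/0", "0/1", "1/1"), n, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25))
        al <- unique(unlist(strsplit(g, "/")))
        if (n == 1L || all(c("0", "1") %in% al)) return(g)
      }
    }

    for (i in seq_len(n_total)) {
      ch <- sel$chrom[i]; pos <- sel$pos[i]
      len <- if (config$indel_min_bp == config$indel_max_bp) config$indel_min_bp
             else sample(config$indel_min_bp:config$indel_max_bp, 1L)
      anchor <- substr(seq_chr[[ch]], pos, pos)
      if (runif(1) < 0.5) { # deletion relative to the reference
        ref <- substr(seq_chr[[ch]], pos, pos + len)
        alt <- anchor
        type <- "deletion"
      } else {             # insertion relative to the reference
        ref <- anchor
        alt <- paste0(anchor, rand_dna(len))
        type <- "insertion"
      }
      cls <- classes[i]
      ga <- groups == "A"
      if (cls == "diagnostic") {
        gt[i, ga] <- "1/1"
        gt[i, !ga] <- "0/0"
        a_allele <- 1L; b_allele <- 0L
      } else if (cls == "shared_polymorphic") {
        gt[i, ga] <- segregating_genos(sum(ga))
        gt[i, !ga] <- segregating_genos(sum(!ga))
        a_allele <- NA_integer_; b_allele <- NA_integer_
      } else {
        carrier <- sample(c("A", "B"), 1L)
        seg <- groups == carrier
        gt[i, seg] <- segregating_genos(sum(seg))
        gt[i, !seg] <- "0/0"
        a_allele <- NA_integer_; b_allele <- NA_integer_
      }
      loci[[i]] <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                              indel_length_bp = abs(nchar(alt) - nchar(ref)),
                              indel_type = type, stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                               class = cls, group_a_allele = a_allele,
                               group_b_allele = b_allele,
                               indel_length_bp = abs(nchar(alt) - nchar(ref)),
                               stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, loci)
    truth <- do.call(rbind, truth)

    if (config$missing_rate > 0 && n_total > 0L) {
      mask <- matrix(runif(n_total * n_s) < config$missing_rate,
                     nrow = n_total)
      gt[mask] <- "./."
    }

    ord <- order(match(loci$chrom, chroms), loci$pos)
    loci <- loci[ord, , drop = FALSE]
    gt <- gt[ord, , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    rownames(loci) <- rownames(truth) <- NULL

    list(matrix = grouped_genotypes(loci, gt, groups), truth = truth)
  })
}

#' Simulate an F1 cross between two individuals
#'
#' At each locus the offspring receives one allele drawn uniformly at random
#' from each parent's genotype; where the parents are homozygous for different
#' alleles the offspring is therefore heterozygous with certainty — the
#' codominant two-band signature used to recognise first-generation hybrids.
#' A missing genotype in either parent yields a missing offspring genotype.
#'
#' @param parent_a,parent_b character vectors of diploid genotypes
#'   (`"0/0"`-style), with identical names (locus ids) in identical order.
#' @param seed integer seed for the allele draws.
#' @return a named character vector of offspring genotypes.
#' @export
simulate_f1 <- function(parent_a, parent_b, seed = 1L) {
  if (length(parent_a) != length(parent_b) ||
      !identical(names(parent_a), names(parent_b))) {
    stop("simulate_f1: parents have mismatched locus sets")
  }
  with_seed(derive_seed(seed, 3L), {
    a <- parse_gt(parent_a)
    b <- parse_gt(parent_b)
    n <- length(parent_a)
    pick_a <- sample.int(2L, n, replace = TRUE)
    pick_b <- sample.int(2L, n, replace = TRUE)
    al1 <- a[cbind(pick_a, seq_len(n))]
    al2 <- b[cbind(pick_b, seq_len(n))]
    setNames(format_gt(al1, al2), names(parent_a))
  })
}

#' Write simulated data to standard file formats
#'
#' Emits the reference FASTA (plus `.fai` index), a VCF v4.2 with per-sample
#' GT fields (positions 1-based, REF/ALT sharing one leading anchor base,
#' missing genotypes as `./.`), a GFF3 gene annotation, a sample-to-group TSV
#' and the truth-table TSV.
#'
#' @param matrix a [grouped_genotypes()] object.
#' @param truth the truth table from [plant_variants()].
#' @param reference a `sim_reference`.
#' @param out_dir output directory (created if absent).
#' @return named character vector of the paths written.
#' @export
write_outputs <- function(matrix, truth, reference, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_outputs: cannot create directory '", out_dir, "'")
  }
  paths <- c(
    fasta = file.path(out_dir, "reference.fa"),
    vcf = file.path(out_dir, "variants.vcf"),
    gff = file.path(out_dir, "genes.gff3"),
    groups = file.path(out_dir, "groups.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(reference$sequences, paths[["fasta"]])
  Rsamtools::indexFa(paths[["fasta"]])
  write_vcf(matrix, reference$sequences, paths[["vcf"]])
  rtracklayer::export(as_gff_granges(reference$genes), paths[["gff"]],
                      format = "gff3")
  write.table(
    data.frame(sample_id = matrix$samples,
               group = unname(matrix$groups[matrix$samples])),
    paths[["groups"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

# Minimal multi-sample GT-only VCF v4.2 writer.
write_vcf <- function(matrix, sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=diagindel",
    sprintf("##contig=<ID=%s,length=%d>", names(sequences), width(sequences)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", matrix$samples), collapse = "\t")
  ), con)
  if (nrow(matrix$loci) > 0L) {
    body <- paste(matrix$loci$chrom, matrix$loci$pos, ".", matrix$loci$ref,
                  matrix$loci$alt, ".", "PASS", ".", "GT",
                  apply(matrix$gt, 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' @importFrom Biostrings width
as_gff_granges <- function(genes) {
  tx <- genes$transcripts; ex <- genes$exons; cd <- genes$cds
  mk <- function(chrom, start, end, strand, type, id, parent) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id
    S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
      lapply(parent, function(p) if (is.na(p)) character(0) else p))
    gr
  }
  strand_of <- setNames(tx$strand, tx$transcript_id)
  g <- mk(tx$chrom, tx$start, tx$end, tx$strand, "gene", tx$gene_id, NA)
  t <- mk(tx$chrom, tx$start, tx$end, tx$strand, "mRNA", tx$transcript_id,
          tx$gene_id)
  e <- mk(ex$chrom, ex$start, ex$end, strand_of[ex$transcript_id], "exon",
          paste0(ex$transcript_id, ".exon", ave(ex$start, ex$transcript_id,
                                                FUN = seq_along)),
          ex$transcript_id)
  cds <- mk(cd$chrom, cd$start, cd$end, strand_of[cd$transcript_id], "CDS",
            paste0(cd$transcript_id, ".cds", ave(cd$start, cd$transcript_id,
                                                 FUN = seq_along)),
            cd$transcript_id)
  out <- c(g, t, e, cds)
  # phase is only meaningful for CDS; 0 is correct for the first CDS base of
  # these single-frame toy models and keeps the GFF3 well-formed
  S4Vectors::mcols(out)$phase <- ifelse(
    S4Vectors::mcols(out)$type == "CDS", 0L, NA_integer_)
  out[order(as.character(GenomicRanges::seqnames(out)),
            GenomicRanges::start(out))]
}

#' @importFrom stats ave
NULL
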