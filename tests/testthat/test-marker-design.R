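test_that("gc_content computes percent G+C and rejects ambiguity", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content(c("ATGC", "GCGC")), c(50, 100))
  expect_error(gc_content("ATGN"), "ambiguous")
})

test_that("Wallace-rule melting temperatures are exact", {
  expect_equal(melting_temperature("ACGT", method = "wallace"), 12)
  expect_equal(melting_temperature("GGGG", method = "wallace"), 16)
  expect_equal(melting_temperature("AATT", method = "wallace"), 8)
})

test_that("nearest-neighbor Tm matches an independent reference implementation", {
  # reference values from Biopython MeltingTemp.Tm_NN with the same parameter
  # set (SantaLucia & Hicks 2004 unified table, 0.368(N-1)ln[Na+] salt
  # correction, Na = 50 mM, 250 nM per primer)
  ref <- c(ACGTACGTACGTACGTACGT = 56.0786,
           ATGCAAATTTGGGCCCATGCAAT = 59.5249,
           GGGCGCATTACGCAT = 52.8499,
           TTTTTTTTTTTTTTTTTT = 35.0183,
           GACTGGTCAAGCTTGACCAG = 55.7992,
           CAGTCTTGAGGACTTCACCTGA = 56.3042)
  got <- melting_temperature(names(ref), method = "nn")
  expect_true(all(abs(got - unname(ref)) < 0.5))
})

test_that("tiers partition InDel lengths into mutually exclusive intervals", {
  expect_equal(indel_tier(c(55L, 45L, 35L, 25L)), c(">50", ">40", ">34", ">20"))
  expect_equal(indel_tier(c(51L, 50L, 41L, 40L, 35L, 34L, 21L)),
               c(">50", ">40", ">40", ">34", ">34", ">20", ">20"))
  cand <- data.frame(tier = c(">50", ">20", ">20"))
  tc <- tier_counts(cand)
  expect_equal(tc$count, c(1L, 0L, 0L, 2L))
  expect_equal(sum(tc$count), nrow(cand))
  expect_equal(tier_counts(data.frame(tier = character()))$count, rep(0L, 4))
})

design_fixture <- function(seed) {
  cfg <- simulation_config(seed = seed, n_chromosomes = 1L,
                           chrom_length = 60000L, n_diagnostic = 10L,
                           n_shared_polymorphic = 5L,
                           n_private_polymorphic = 5L,
                           indel_min_bp = 15L, indel_max_bp = 60L)
  ref <- simulate_reference(cfg)
  pl <- plant_variants(ref, cfg)
  list(cfg = cfg, ref = ref, calls = scan_diagnostic(pl$matrix))
}

test_that("designed candidates satisfy every constraint and the amplicon identity", {
  fx <- design_fixture(41)
  cn <- primer_constraints()
  cand <- design_candidates(fx$calls, fx$ref, cn)
  expect_gt(nrow(cand), 0)

  # threshold: loci at or below min_indel_length never designed
  expect_true(all(cand$indel_length_bp > cn$min_indel_length))

  # amplicon-difference identity: |ref - alt| = InDel length, always
  expect_equal(abs(cand$amplicon_ref - cand$amplicon_alt),
               cand$indel_length_bp)

  # size / Tm / GC / primer length bounds on both primers and both alleles
  for (a in c(cand$amplicon_ref, cand$amplicon_alt)) {
    expect_gte(a, cn$amplicon_min); expect_lte(a, cn$amplicon_max)
  }
  for (tm in c(cand$tm_f, cand$tm_r)) {
    expect_gte(tm, cn$tm_min); expect_lte(tm, cn$tm_max)
  }
  for (gc in c(cand$gc_f, cand$gc_r)) {
    expect_gte(gc, cn$gc_min); expect_lte(gc, cn$gc_max)
  }
  expect_true(all(nchar(cand$fwd_seq) >= cn$primer_len_min &
                    nchar(cand$fwd_seq) <= cn$primer_len_max))
  expect_true(all(nchar(cand$rev_seq) >= cn$primer_len_min &
                    nchar(cand$rev_seq) <= cn$primer_len_max))

  # the InDel lies strictly between the primer binding sites
  expect_true(all(cand$fwd_end <= cand$pos))
  expect_true(all(cand$rev_start > cand$pos + nchar(cand$ref) - 1L))

  # primer sequences really come from the reference (fwd plus, rev minus)
  seqs <- as.character(fx$ref$sequences)
  for (i in seq_len(nrow(cand))) {
    tpl <- seqs[[cand$chrom[i]]]
    expect_identical(substr(tpl, cand$fwd_start[i], cand$fwd_end[i]),
                     cand$fwd_seq[i])
    expect_identical(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(tpl, cand$rev_start[i], cand$rev_end[i])))),
      cand$rev_seq[i])
  }

  # input (length-descending) order is preserved
  expect_true(all(diff(cand$indel_length_bp) <= 0))
})

test_that("design matches a brute-force enumeration oracle", {
  # small amplicons and the hand-checkable Wallace rule keep the exhaustive
  # oracle tractable
  cn <- primer_constraints(amplicon_min = 60, amplicon_max = 120,
                           tm_min = 40, tm_max = 75, gc_min = 30, gc_max = 70,
                           primer_len_min = 18, primer_len_max = 22,
                           min_indel_length = 20, tm_method = "wallace")
  for (seed in c(101, 202, 303)) {
    withr::with_seed(seed, {
      left <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                    collapse = "")
      right <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                     collapse = "")
      ins <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                   collapse = "")
    })
    pos <- 200L
    anchor <- substr(left, 200, 200)
    tpl <- paste0(left, right)
    call <- data.frame(chrom = "chr1", pos = pos, ref = anchor,
                       alt = paste0(anchor, ins), indel_length_bp = 25L,
                       indel_type = "insertion", group_a_allele = 1L,
                       group_b_allele = 0L, n_missing_a = 0L, n_missing_b = 0L,
                       locus_index = 1L, stringsAsFactors = FALSE)
    got <- design_candidates(call, Biostrings::DNAStringSet(c(chr1 = tpl)),
                             cn, uniqueness_window = 0L)
    want <- oracle_design(call, tpl, cn)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L, label = paste("seed", seed))
    } else {
      expect_equal(nrow(got), 1L)
      for (f in c("fwd_seq", "rev_seq", "fwd_start", "fwd_end", "rev_start",
                  "rev_end", "amplicon_ref", "amplicon_alt")) {
        expect_equal(got[[f]], want[[f]], label = paste("seed", seed, f))
      }
    }
  }
})

test_that("repeated flanks defeat the local uniqueness screen", {
  withr::with_seed(7, {
    flank <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = "")
    ins <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
  })
  # duplicate the whole locus neighborhood so no local primer can be unique
  tpl <- paste0(flank, flank)
  pos <- 150L
  anchor <- substr(tpl, pos, pos)
  call <- data.frame(chrom = "chr1", pos = pos, ref = anchor,
                     alt = paste0(anchor, ins), indel_length_bp = 30L,
                     indel_type = "insertion", group_a_allele = 1L,
                     group_b_allele = 0L, n_missing_a = 0L, n_missing_b = 0L,
                     locus_index = 1L, stringsAsFactors = FALSE)
  cn <- primer_constraints(amplicon_min = 60, amplicon_max = 120,
                           tm_min = 30, tm_max = 90, gc_min = 10, gc_max = 90,
                           primer_len_min = 18, primer_len_max = 22,
                           min_indel_length = 20, tm_method = "wallace")
  dup <- design_candidates(call, Biostrings::DNAStringSet(c(chr1 = tpl)), cn,
                           max_uniqueness_tries = 200L)
  expect_equal(nrow(dup), 0L)
  expect_match(attr(dup, "skipped")$reason, "unique")
  # the same locus designs fine when the screen is off
  ok <- design_candidates(call, Biostrings::DNAStringSet(c(chr1 = tpl)), cn,
                          uniqueness_window = 0L)
  expect_equal(nrow(ok), 1L)
})

test_that("loci near a contig edge are skipped with a reason", {
  withr::with_seed(13, {
    tpl <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                 collapse = "")
  })
  call <- data.frame(chrom = "chr1", pos = 10L, ref = substr(tpl, 10, 40),
                     alt = substr(tpl, 10, 10), indel_length_bp = 30L,
                     indel_type = "deletion", group_a_allele = 1L,
                     group_b_allele = 0L, n_missing_a = 0L, n_missing_b = 0L,
                     locus_index = 1L, stringsAsFactors = FALSE)
  got <- design_candidates(call, Biostrings::DNAStringSet(c(chr1 = tpl)))
  expect_equal(nrow(got), 0L)
  expect_equal(nrow(attr(got, "skipped")), 1L)
})
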