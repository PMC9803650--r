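test_that("classify_locus applies the fixed-difference condition", {
  # the extraction condition with 7 + 7 samples: fixed for different alleles
  m <- toy_matrix(rep("0/0", 7), rep("1/1", 7))
  cl <- classify_locus(m, 1)
  expect_equal(cl$status, "diagnostic")
  expect_equal(cl$group_a_allele, 0L)
  expect_equal(cl$group_b_allele, 1L)

  # monomorphic across both groups
  expect_equal(classify_locus(toy_matrix(rep("0/0", 7), rep("0/0", 7)), 1)$status,
               "non_diagnostic")
  # a single heterozygote breaks within-group homozygosity
  expect_equal(classify_locus(toy_matrix(c("0/0", "0/1"), c("1/1", "1/1")), 1)$status,
               "non_diagnostic")
  # missingness beyond policy is indeterminate, within policy still diagnostic
  m_miss <- toy_matrix(c("0/0", "./."), c("1/1", "1/1"))
  expect_equal(classify_locus(m_miss, 1, max_missing = 0)$status, "indeterminate")
  expect_equal(classify_locus(m_miss, 1, max_missing = 1)$status, "diagnostic")
  # half-calls count as missing
  m_half <- toy_matrix(c("0/0", "0/."), c("1/1", "1/1"))
  expect_equal(classify_locus(m_half, 1, max_missing = 0)$status, "indeterminate")
  expect_equal(classify_locus(m_half, 1, max_missing = 1)$status, "diagnostic")
})

test_that("classify_locus matches the exhaustive brute-force oracle", {
  # all biallelic configurations for 3 + 3 samples
  genos <- c("0/0", "0/1", "1/1", "./.")
  grid <- expand.grid(rep(list(genos), 6), stringsAsFactors = FALSE)
  for (policy in c(0L, 1L)) {
    got <- apply(grid, 1, function(g) {
      classify_locus(toy_matrix(g[1:3], g[4:6]), 1, max_missing = policy)$status
    })
    want <- apply(grid, 1, function(g) {
      oracle_classify(g[1:3], g[4:6], max_missing = policy)
    })
    expect_identical(got, want)
  }

  # 2 + 2 samples with two alternate alleles
  genos2 <- c("0/0", "0/1", "1/1", "0/2", "1/2", "2/2", "./.")
  grid2 <- expand.grid(rep(list(genos2), 4), stringsAsFactors = FALSE)
  got <- apply(grid2, 1, function(g) {
    classify_locus(toy_matrix(g[1:2], g[3:4]), 1)$status
  })
  want <- apply(grid2, 1, function(g) oracle_classify(g[1:2], g[3:4]))
  expect_identical(got, want)
})

test_that("scan orders by InDel length descending with (chrom,pos) tie-break", {
  samples <- c("A1", "B1")
  groups <- setNames(c("A", "B"), samples)
  loci <- data.frame(
    chrom = c("chr2", "chr1", "chr1", "chr1"),
    pos = c(100L, 900L, 200L, 500L),
    ref = c("ATTTT", "ATTTT", "ATT", "A"),
    alt = c("A", "A", "A", "ATTTTTTT"),
    stringsAsFactors = FALSE)
  loci$indel_length_bp <- abs(nchar(loci$alt) - nchar(loci$ref))
  loci$indel_type <- ifelse(nchar(loci$alt) > nchar(loci$ref),
                            "insertion", "deletion")
  gt <- matrix("0/0", nrow = 4, ncol = 2, dimnames = list(NULL, samples))
  gt[, "A1"] <- "1/1"
  m <- grouped_genotypes(loci, gt, groups)
  sc <- scan_diagnostic(m)
  expect_equal(sc$indel_length_bp, c(7L, 4L, 4L, 2L))
  # equal lengths: chr1 before chr2, then ascending position
  expect_equal(sc$chrom[2:3], c("chr1", "chr2"))
  expect_equal(sc$pos[2:3], c(900L, 100L))
})

test_that("scan recovers exactly the planted diagnostic loci", {
  cfg <- simulation_config(seed = 21, n_chromosomes = 1L,
                           chrom_length = 60000L, n_diagnostic = 8L,
                           n_shared_polymorphic = 10L,
                           n_private_polymorphic = 10L, missing_rate = 0)
  pl <- plant_variants(simulate_reference(cfg), cfg)
  sc <- scan_diagnostic(pl$matrix)
  planted <- pl$truth[pl$truth$class == "diagnostic", ]
  expect_setequal(paste(sc$chrom, sc$pos), paste(planted$chrom, planted$pos))
})

test_that("a masked genotype is tolerated when the policy allows it", {
  cfg <- simulation_config(seed = 22, n_chromosomes = 1L,
                           chrom_length = 60000L, n_diagnostic = 5L,
                           n_shared_polymorphic = 5L,
                           n_private_polymorphic = 5L, missing_rate = 0)
  pl <- plant_variants(simulate_reference(cfg), cfg)
  i <- which(pl$truth$class == "diagnostic")[1]
  pl$matrix$gt[i, "A1"] <- "./."
  sc0 <- scan_diagnostic(pl$matrix, max_missing = 0)
  sc1 <- scan_diagnostic(pl$matrix, max_missing = 1)
  key <- paste(pl$truth$chrom[i], pl$truth$pos[i])
  expect_false(key %in% paste(sc0$chrom, sc0$pos))
  expect_true(key %in% paste(sc1$chrom, sc1$pos))
})

test_that("the diagnostic set grows monotonically with the missingness policy", {
  cfg <- simulation_config(seed = 23, n_chromosomes = 1L,
                           chrom_length = 100000L, n_diagnostic = 20L,
                           n_shared_polymorphic = 20L,
                           n_private_polymorphic = 20L, missing_rate = 0.08)
  pl <- plant_variants(simulate_reference(cfg), cfg)
  sets <- lapply(0:3, function(k) {
    sc <- scan_diagnostic(pl$matrix, max_missing = k)
    paste(sc$chrom, sc$pos)
  })
  for (k in 1:3) expect_true(all(sets[[k]] %in% sets[[k + 1]]))
})

test_that("summarize_samples counts the four genotype classes exhaustively", {
  samples <- c("A1", "B1")
  groups <- setNames(c("A", "B"), samples)
  loci <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                     ref = "ATT", alt = "A", indel_length_bp = 2L,
                     indel_type = "deletion", stringsAsFactors = FALSE)
  gt <- cbind(A1 = c("0/0", "1/1", "0/1", "./."),
              B1 = c("0/0", "0/0", "0/0", "0/0"))
  s <- summarize_samples(grouped_genotypes(loci, gt, groups))
  a <- s[s$sample_id == "A1", ]
  expect_equal(c(a$n_ref_homo, a$n_alt_homo, a$n_het, a$n_missing, a$n_total),
               c(1L, 1L, 1L, 1L, 4L))

  # conservation + reference polarity on simulated data
  cfg <- simulation_config(seed = 24, n_chromosomes = 1L,
                           chrom_length = 60000L, n_diagnostic = 8L,
                           n_shared_polymorphic = 10L,
                           n_private_polymorphic = 10L, missing_rate = 0)
  pl <- plant_variants(simulate_reference(cfg), cfg)
  s <- summarize_samples(pl$matrix)
  expect_true(all(s$n_ref_homo + s$n_alt_homo + s$n_het + s$n_missing ==
                    s$n_total))
  expect_true(all(s$n_missing == 0))
  # group A is homozygous-alt at every diagnostic locus
  expect_true(all(s$n_alt_homo[s$group == "A"] >= cfg$n_diagnostic))
})

test_that("load_matrix filters SNPs and decomposes multiallelic records", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "mini.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tATT\t.\tPASS\t.\tGT\t0/1\t1/1",     # insertion
    "chr1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",       # SNP: skipped
    "chr1\t300\t.\tATTT\tA\t.\tPASS\t.\tGT\t0/0\t1/1",    # deletion
    "chr1\t400\t.\tG\tC\t.\tPASS\t.\tGT\t1/1\t0/0",       # SNP: skipped
    "chr1\t500\t.\tA\tAT,ATT\t.\tPASS\t.\tGT\t0/1\t1/2"   # multiallelic
  ), vcf)
  groups <- data.frame(sample_id = c("S1", "S2"), group = c("A", "B"))
  expect_message(m <- load_matrix(vcf, groups), "skipped 2")
  expect_equal(nrow(m$loci), 4L) # 2 simple indels + 2 decomposed alts
  dec <- m$loci$pos == 500L
  expect_equal(sum(dec), 2L)
  # decomposition: alleles of the other alt become missing
  expect_equal(unname(m$gt[m$loci$pos == 500 & m$loci$alt == "AT", ]),
               c("0/1", "./."))
  expect_equal(unname(m$gt[m$loci$pos == 500 & m$loci$alt == "ATT", ]),
               c("./.", "./."))

  # sample absent from groups file is a configuration error
  expect_error(load_matrix(vcf, groups[1, , drop = FALSE]), "absent")

  # empty VCF body gives an empty matrix, not an error
  vcf0 <- file.path(dir, "empty.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2"
  ), vcf0)
  m0 <- suppressWarnings(load_matrix(vcf0, groups, quiet = TRUE))
  expect_equal(nrow(m0$loci), 0L)
  expect_equal(nrow(scan_diagnostic(m0)), 0L)
})
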