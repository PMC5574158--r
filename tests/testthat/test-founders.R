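test_that("Beta-drawn frequencies give a U-shaped spectrum and are reproducible", {
  p <- draw_site_frequencies(1e4, 0.2, seed = 1)
  expect_true(all(p > 0 & p < 1))
  # Beta(0.2, 0.2) tail mass below 0.1 / above 0.9 is ~0.66 before the
  # polymorphism truncation redraws the near-fixed extremes
  expect_gt(mean(p < 0.1 | p > 0.9), 0.5)
  expect_lt(mean(p < 0.1 | p > 0.9), 0.75)
  expect_identical(p, draw_site_frequencies(1e4, 0.2, seed = 1))
  p1 <- draw_site_frequencies(1, 1.0, seed = 2)
  expect_true(p1 > 0 && p1 < 1)
  expect_error(draw_site_frequencies(0, 0.2), class = "episel_invalid_parameter")
  expect_error(draw_site_frequencies(10, -1), class = "episel_invalid_parameter")
})

test_that("inbred founder lines are fully homozygous and fixed sites stay fixed", {
  freqs <- c(rep(0.5, 20), 1.0)
  panel <- make_founder_panel(freqs, 12, inbred = TRUE, seed = 3)
  odd <- panel$H[seq(1, 24, 2), ]
  even <- panel$H[seq(2, 24, 2), ]
  expect_identical(odd, even)              # zero heterozygosity per line
  expect_true(all(panel$H[, 21] == 1L))    # degenerate Bernoulli(1)
  # polymorphism enforced where 0 < p < 1
  cs <- colSums(panel$H[, 1:20])
  expect_true(all(cs > 0 & cs < 24))
  expect_identical(panel$H,
                   make_founder_panel(freqs, 12, inbred = TRUE, seed = 3)$H)
})

test_that("independent sites give near-zero long-range LD in the panel", {
  p <- draw_site_frequencies(4000, 0.2, seed = 4)
  panel <- make_founder_panel(p, 205, seed = 5)
  lines <- panel$H[seq(1, nrow(panel$H), 2), ]
  sites <- panel$sites
  set.seed(6)
  # inter-chromosome pairs
  i <- sample(which(sites$chrom == "2"), 1000, replace = TRUE)
  j <- sample(which(sites$chrom == "3"), 1000, replace = TRUE)
  r2 <- vapply(seq_along(i),
               function(k) cor(lines[, i[k]], lines[, j[k]])^2, 0)
  expect_lte(median(r2), 2 / 205)
  # within-chromosome pairs more than 1 Mb apart
  ii <- which(sites$chrom == "2")
  prs <- cbind(sample(ii, 2000, TRUE), sample(ii, 2000, TRUE))
  prs <- prs[abs(sites$pos_bp[prs[, 1]] - sites$pos_bp[prs[, 2]]) > 1e6, ]
  r2w <- vapply(seq_len(nrow(prs)),
                function(k) cor(lines[, prs[k, 1]], lines[, prs[k, 2]])^2, 0)
  expect_lt(mean(r2w), 0.02)
})

test_that("the genetic map interpolates linearly and is zero for males", {
  chromosomes <- data.frame(chrom = "2", length_bp = 1e6, length_cm = 100)
  sites <- data.frame(site_id = 1:3, chrom = "2",
                      pos_bp = c(1L, 5e5L, 5e5L),
                      ref_allele = "A", alt_allele = "T")
  m <- make_genetic_map(sites, chromosomes)
  expect_equal(m$cm_female[2], 50)
  expect_equal(m$cm_female[2], m$cm_female[3])  # same bp -> same cM
  expect_true(all(m$cm_male == 0))
  bad <- sites; bad$chrom <- "17"
  expect_error(make_genetic_map(bad, chromosomes),
               class = "episel_invalid_parameter")
  # breakpoint table overrides the uniform map
  bk <- data.frame(chrom = "2", bp = c(0, 2e5, 1e6), cm = c(0, 80, 100))
  mb <- make_genetic_map(sites, chromosomes, breakpoints = bk)
  expect_equal(mb$cm_female[1], 0, tolerance = 1e-3)
  expect_gt(mb$cm_female[2], 80)
})

test_that("VCF ingestion keeps phased biallelic SNPs and rejects the rest", {
  sites <- make_site_table(50, seed = 7)
  pick <- sites[c(5, 10, 15, 20), ]
  vcf <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "L1", "L2", sep = "\t"))
  rec <- function(chrom, pos, ref, alt, g1, g2)
    paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", g1, g2,
          sep = "\t")
  writeLines(c(hdr,
               rec(pick$chrom[1], pick$pos_bp[1], "A", "T", "0|0", "1|1"),
               rec(pick$chrom[2], pick$pos_bp[2], "C", "G", "0|1", "1|0"),
               rec(pick$chrom[3], pick$pos_bp[3], "A", "AT", "0|0", "0|0"),
               rec(pick$chrom[4], pick$pos_bp[4], "G", "C", "1|1", "0|0")),
             vcf)
  panel <- suppressMessages(load_haplotypes_vcf(vcf, sites))
  expect_equal(nrow(panel$sites), 3L)      # the indel record is skipped
  expect_equal(length(panel$line_ids), 2L)
  expect_equal(panel$H[, panel$sites$pos_bp == pick$pos_bp[2]],
               c(0L, 1L, 1L, 0L))
  # missing genotypes: dropped by default, error when strict
  writeLines(c(hdr,
               rec(pick$chrom[1], pick$pos_bp[1], "A", "T", "0|0", "1|1"),
               rec(pick$chrom[2], pick$pos_bp[2], "C", "G", ".", "1|0")),
             vcf)
  expect_equal(nrow(suppressMessages(load_haplotypes_vcf(vcf, sites))$sites),
               1L)
  expect_error(suppressMessages(load_haplotypes_vcf(vcf, sites,
                                                    strict = TRUE)),
               class = "episel_invalid_parameter")
  # unphased genotypes are rejected
  writeLines(c(hdr,
               rec(pick$chrom[1], pick$pos_bp[1], "A", "T", "0/0", "1/1")),
             vcf)
  expect_error(suppressMessages(load_haplotypes_vcf(vcf, sites)),
               class = "episel_invalid_parameter")
  expect_error(load_haplotypes_vcf(tempfile(), sites),
               class = "episel_invalid_parameter")
})
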