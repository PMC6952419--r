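cfg <- filter_config()

ann_row <- function(...) {
  a <- data.frame(QD = NA_real_, FS = NA_real_, MQ = NA_real_,
                  MQRankSum = NA_real_, ReadPosRankSum = NA_real_,
                  SOR = NA_real_)
  set <- list(...)
  for (k in names(set)) a[[k]] <- set[[k]]
  a
}

test_that("SNV hard filters fail only on present, violating annotations", {
  r <- apply_snv_hard_filters(ann_row(QD = 1.9), cfg)
  expect_false(r$pass)
  expect_equal(r$reasons, "QD")
  # all annotations absent: vacuously passes
  expect_true(apply_snv_hard_filters(ann_row(), cfg)$pass)
  # all six inequalities satisfied
  r <- apply_snv_hard_filters(
    ann_row(QD = 30, FS = 0.5, MQ = 60, MQRankSum = 0, ReadPosRankSum = 0,
            SOR = 1.0), cfg)
  expect_true(r$pass)
  # multiple violations are all recorded
  r <- apply_snv_hard_filters(ann_row(FS = 61, SOR = 3.5), cfg)
  expect_false(r$pass)
  expect_equal(r$reasons, "FS,SOR")
})

test_that("indel hard filters use the indel thresholds with strict inequalities", {
  expect_false(apply_indel_hard_filters(ann_row(FS = 250), cfg)$pass)
  expect_equal(apply_indel_hard_filters(ann_row(FS = 250), cfg)$reasons,
               "FS")
  # FS = 150 fails the SNV rule but passes the indel rule
  expect_true(apply_indel_hard_filters(ann_row(FS = 150), cfg)$pass)
  expect_false(apply_snv_hard_filters(ann_row(FS = 150), cfg)$pass)
  # boundary of a strict ">": SOR exactly 10 passes
  expect_true(apply_indel_hard_filters(ann_row(SOR = 10.0), cfg)$pass)
  expect_false(apply_indel_hard_filters(ann_row(SOR = 10.0001), cfg)$pass)
})

test_that("excess-depth cutoff is d + 3 sqrt(d)", {
  expect_identical(excessive_depth_cutoff(100), 130)
  expect_equal(excessive_depth_cutoff(60), 60 + 3 * sqrt(60),
               tolerance = 1e-12)
  expect_identical(excessive_depth_cutoff(1), 4)
  expect_error(excessive_depth_cutoff(0), "> 0")
  expect_error(excessive_depth_cutoff(-5), "> 0")
})

test_that("sample-level filter applies genotype, depth bounds and AF", {
  r <- sample_level_filter("0/1", 58L, 6L, 64L, cfg)
  expect_false(r$pass)            # af = 6/64 < 0.10
  expect_false(r$allele_fraction)
  expect_true(r$genotype && r$min_depth && r$excess_depth)

  r <- sample_level_filter("0/0", 60L, 0L, 60L, cfg)
  expect_false(r$genotype)
  expect_true(r$min_depth && r$excess_depth)

  r <- sample_level_filter("0/1", 5L, 4L, 9L, cfg)
  expect_false(r$min_depth)
  expect_true(r$genotype && r$excess_depth && r$allele_fraction)

  # excess depth: strictly above d + 3 sqrt(d) = 83.24 fails
  expect_true(sample_level_filter("0/1", 40L, 43L, 83L, cfg)$excess_depth)
  expect_false(sample_level_filter("0/1", 42L, 42L, 84L, cfg)$excess_depth)

  # unevaluable AF (missing AD) fails the AF condition
  r <- sample_level_filter("0/1", NA, NA, 60L, cfg)
  expect_false(r$allele_fraction)
  # af exactly at the threshold passes (>=)
  expect_true(sample_level_filter("0/1", 54L, 6L, 60L, cfg)$allele_fraction)
})

test_that("SNVs within +/-5 bp of an indel border are removed", {
  deln <- data.frame(chrom = "chr1", pos = 100L, ref = "ACGT", alt = "A")
  snv <- function(pos, chrom = "chr1") {
    data.frame(chrom = chrom, pos = pos, ref = "C", alt = "T")
  }
  # borders at 100 and 103; distance 2 -> removed
  expect_false(remove_near_indel(snv(105), deln, cfg))
  # distance 6 -> kept
  expect_true(remove_near_indel(snv(109), deln, cfg))
  expect_false(remove_near_indel(snv(108), deln, cfg))
  expect_false(remove_near_indel(snv(95), deln, cfg))
  expect_true(remove_near_indel(snv(94), deln, cfg))
  # no indel on the chromosome: kept
  expect_true(remove_near_indel(snv(105, "chr2"), deln, cfg))
  # insertion borders are pos and pos + 1
  ins <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "ATTT")
  expect_false(remove_near_indel(snv(106), ins, cfg))
  expect_true(remove_near_indel(snv(107), ins, cfg))
})

sv_fixture <- function(qual, su, gt = "0/1", dp = 60,
                       chrom = "chr1", start = 1000L, end = 1200L) {
  structure(list(
    records = data.frame(chrom = chrom, start = start, end = end,
                         svtype = "DEL", qual = qual, su = su),
    gt = matrix(gt, 1, 1, dimnames = list(NULL, "K1")),
    dp = matrix(dp, 1, 1, dimnames = list(NULL, "K1")),
    samples = "K1"), class = "sv_set")
}

test_that("complex-indel filtering applies genotype, QUAL, coverage, SU and mask", {
  r <- filter_complex_indels(sv_fixture(qual = 99, su = 20), "K1", cfg)
  expect_false(r$pass); expect_false(r$quality); expect_true(r$su)
  r <- filter_complex_indels(sv_fixture(qual = 500, su = 4), "K1", cfg)
  expect_false(r$pass); expect_false(r$su); expect_true(r$quality)
  r <- filter_complex_indels(sv_fixture(qual = 500, su = 5), "K1", cfg)
  expect_true(r$pass)
  r <- filter_complex_indels(sv_fixture(qual = 500, su = 5, gt = "0/0"),
                             "K1", cfg)
  expect_false(r$pass); expect_false(r$genotype)
  r <- filter_complex_indels(sv_fixture(qual = 500, su = 5, dp = 200),
                             "K1", cfg)
  expect_false(r$coverage)
  mask <- mask_from_df(data.frame(chrom = "chr1", start = 1100, end = 1150))
  r <- filter_complex_indels(sv_fixture(qual = 500, su = 5), "K1", cfg,
                             mask = mask)
  expect_false(r$mask)
})

test_that("simple indels overlapping complex intervals are excluded (half-open)", {
  cx <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  simple <- function(pos, ref = "ACG") {
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = "A")
  }
  # contained -> removed
  expect_false(exclude_sv_overlapping_simple_indels(simple(150), cx))
  # far away -> kept
  expect_true(exclude_sv_overlapping_simple_indels(simple(1150), cx))
  # abutting the half-open end (1-based 201) -> kept
  expect_true(exclude_sv_overlapping_simple_indels(simple(201), cx))
  # last covered base (1-based 200) -> removed
  expect_false(exclude_sv_overlapping_simple_indels(simple(200, "AC"), cx))
  # straddling the start -> removed
  expect_false(exclude_sv_overlapping_simple_indels(simple(99, "ACGT"), cx))
})

test_that("parental subtraction matches alleles, not sites", {
  child <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                      ref = c("A", "C", "G"), alt = c("T", "G", "A"))
  dam <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "T")
  sire <- data.frame(chrom = "chr1", pos = 30L, ref = "G", alt = "C")
  keep <- subtract_parental(child, sire, dam)
  # pos 10: same allele in dam -> excluded; pos 30: different alt -> kept
  expect_equal(keep, c(FALSE, TRUE, TRUE))
  # both parents empty -> all retained
  expect_true(all(subtract_parental(child, NULL, NULL)))
})
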