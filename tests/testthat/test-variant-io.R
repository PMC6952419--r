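test_that("multi-allelic records are split with per-alt AD slices and GT remapping", {
  p <- write_fixture_vcf(c(
    "chr1\t100\t.\tA\tT,G\t.\t.\tQD=1.9;SOR=3.5\tGT:AD:DP\t0/1:50,3,2:55\t1/2:10,20,30:60",
    "chr1\t200\t.\tC\tT\t.\t.\t.\tGT:AD:DP\t0/0:60,0:60\t./.:.:."))
  vs <- read_multisample_vcf(p)
  expect_equal(nrow(vs$variants), 3)
  expect_equal(vs$variants$alt[1:2], c("T", "G"))
  expect_equal(vs$variants$pos[1:2], c(100L, 100L))
  # AD re-sliced per alternate allele
  expect_equal(unname(vs$ad_alt[1, "S1"]), 3L)
  expect_equal(unname(vs$ad_alt[2, "S1"]), 2L)
  expect_equal(vs$ad_ref[1:2, "S1"], c(50L, 50L), ignore_attr = TRUE)
  # GT mapped onto the retained alternate: S2 is 1/2 -> het for each alt
  expect_equal(vs$gt[1:2, "S2"], c("0/1", "0/1"), ignore_attr = TRUE)
  expect_equal(unname(vs$gt[1, "S1"]), "0/1")
  expect_equal(unname(vs$gt[2, "S1"]), "0/0")
  # INFO mapping: present keys parsed, absent keys NA (never zero)
  expect_equal(vs$variants$QD[1], 1.9)
  expect_equal(vs$variants$SOR[1], 3.5)
  expect_true(is.na(vs$variants$FS[1]))
  expect_true(is.na(vs$variants$QD[3]))
  # missing genotype
  expect_true(is.na(vs$gt[3, "S2"])[[1]])
})

test_that("splitting conserves the number of (site, alt) pairs", {
  body <- c("chr1\t10\t.\tA\tT,G,C\t.\t.\t.\tGT:AD:DP\t0/1:5,1,1,1:8\t0/0:8,0,0,0:8",
            "chr1\t20\t.\tC\tG\t.\t.\t.\tGT:AD:DP\t0/1:4,4:8\t0/1:4,4:8",
            "chr2\t30\t.\tG\tA,T\t.\t.\t.\tGT:AD:DP\t1/2:0,4,4:8\t0/0:8,0,0:8")
  vs <- read_multisample_vcf(write_fixture_vcf(body))
  expect_equal(nrow(vs$variants), 3 + 1 + 2)
  expect_equal(anyDuplicated(variant_key(vs$variants)), 0L)
})

test_that("empty VCF body still yields the sample order", {
  vs <- read_multisample_vcf(write_fixture_vcf(character(0),
                                               samples = c("A", "B", "C")))
  expect_equal(nrow(vs$variants), 0)
  expect_equal(vs$samples, c("A", "B", "C"))
})

test_that("malformed VCFs produce parse errors naming the problem line", {
  bad_hdr <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "chr1\t1\t.\tA\tT"), bad_hdr)
  expect_error(read_multisample_vcf(bad_hdr), "malformed VCF header")
  p <- write_fixture_vcf(c(
    "chr1\t100\t.\tA\tT\t.\t.\t.\tGT:AD:DP\t0/1:5,5:10\t0/1:5,5:10",
    "chr1\t200\t.\tC\tG\t.\t.\t.\tGT:AD:DP\t0/1:5,5:10"))
  expect_error(read_multisample_vcf(p), "line 15")
})

test_that("VCF round-trip preserves coordinates, alleles, GT, AD and DP", {
  for (seed in 1:4) {
    mc <- rand_mini_cohort(seed)
    path <- tempfile(fileext = ".vcf")
    write_variant_vcf(mc$vs, path)
    back <- read_multisample_vcf(path)
    ord1 <- order(mc$vs$variants$chrom, mc$vs$variants$pos,
                  mc$vs$variants$alt)
    ord2 <- order(back$variants$chrom, back$variants$pos,
                  back$variants$alt)
    for (f in c("chrom", "pos", "ref", "alt")) {
      expect_equal(back$variants[[f]][ord2], mc$vs$variants[[f]][ord1])
    }
    for (m in c("gt", "ad_ref", "ad_alt", "dp")) {
      expect_equal(back[[m]][ord2, , drop = FALSE],
                   mc$vs[[m]][ord1, , drop = FALSE],
                   ignore_attr = TRUE)
    }
  }
})

test_that("BED reading unions, merges and validates intervals", {
  p1 <- write_fixture_bed(c("chr1\t10\t20", "chr1\t15\t30"))
  m <- read_intervals_bed(p1)
  expect_equal(length(m), 1)
  expect_equal(GenomicRanges::start(m), 11)
  expect_equal(GenomicRanges::end(m), 30)
  # two files with disjoint chromosomes are both present
  p2 <- write_fixture_bed("chr2\t5\t9")
  m2 <- read_intervals_bed(c(p1, p2))
  expect_equal(length(m2), 2)
  expect_setequal(as.character(GenomicRanges::seqnames(m2)),
                  c("chr1", "chr2"))
  # invalid interval errors with the line number
  p3 <- write_fixture_bed(c("chr1\t1\t5", "chr1\t20\t10"))
  expect_error(read_intervals_bed(p3), "line 2")
})

test_that("mask overlap follows half-open BED semantics over the REF span", {
  mask <- mask_from_df(data.frame(chrom = "chr1", start = 10, end = 20))
  v <- function(pos, ref) data.frame(chrom = "chr1", pos = pos, ref = ref,
                                     alt = "T")
  expect_true(overlaps_mask(v(11, "A"), mask))    # 0-based 10 in [10,20)
  expect_false(overlaps_mask(v(10, "A"), mask))   # 0-based 9 not in [10,20)
  expect_false(overlaps_mask(v(21, "A"), mask))   # 0-based 20 not in [10,20)
  expect_true(overlaps_mask(v(8, "AACGT"), mask)) # deletion spans 8..12
})

test_that("mask overlap agrees with a per-base brute-force oracle", {
  set.seed(42)
  n_cases <- 250
  for (rep in seq_len(n_cases)) {
    k <- sample(1:3, 1)
    mask_df <- data.frame(chrom = sample(c("chr1", "chr2"), k, TRUE),
                          start = sample(0:80, k))
    mask_df$end <- mask_df$start + sample(1:10, k, replace = TRUE)
    mask <- mask_from_df(mask_df)
    v <- data.frame(chrom = sample(c("chr1", "chr2"), 1),
                    pos = sample(1:90, 1),
                    ref = paste(rep("A", sample(1:6, 1)), collapse = ""),
                    alt = "T")
    expect_equal(overlaps_mask(v, mask),
                 oracle_overlaps(v$chrom, v$pos, v$ref, mask_df))
  }
})

test_that("SV VCF reading extracts SVTYPE, END, SU, QUAL and genotypes", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=SU,Number=1,Type=Integer,Description=\"s\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t101\t.\tN\t<DEL>\t250\t.\tSVTYPE=DEL;END=300;SU=12\tGT:DP\t0/1:55\t0/0:62"),
    p)
  sv <- read_sv_vcf(p)
  expect_equal(sv$records$start, 100L)  # half-open 0-based
  expect_equal(sv$records$end, 300L)
  expect_equal(sv$records$svtype, "DEL")
  expect_equal(sv$records$qual, 250)
  expect_equal(sv$records$su, 12L)
  expect_equal(sv$gt[1, ], c(S1 = "0/1", S2 = "0/0"))
  expect_equal(unname(sv$dp[1, "S1"]), 55)
})

test_that("pedigree validation catches structural errors", {
  good <- data.frame(sample_id = c("P1", "P2", "K1"),
                     role = c("parent", "parent", "offspring"),
                     group = c(NA, NA, "ABE"),
                     sire_id = c(NA, NA, "P1"), dam_id = c(NA, NA, "P2"))
  expect_s3_class(pedigree_cohort(good), "pedigree_cohort")
  orphan <- good; orphan$sire_id[3] <- NA; orphan$dam_id[3] <- NA
  expect_error(pedigree_cohort(orphan), "resolvable parent")
  unknown <- good; unknown$dam_id[3] <- "P9"
  expect_error(pedigree_cohort(unknown), "P9")
})
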