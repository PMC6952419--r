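test_that("identical spec and seed produce byte-identical bundles", {
  sp <- small_cohort_spec(101)
  b1 <- simulate_cohort(sp, dir = tempfile())
  b2 <- simulate_cohort(sp, dir = tempfile())
  for (f in names(b1$paths)) {
    expect_identical(unname(tools::md5sum(b1$paths[[f]])),
                     unname(tools::md5sum(b2$paths[[f]])),
                     label = paste("md5 of", f))
  }
  b3 <- simulate_cohort(small_cohort_spec(102), dir = tempfile())
  expect_false(identical(unname(tools::md5sum(b1$paths[["vcf"]])),
                         unname(tools::md5sum(b3$paths[["vcf"]]))))
})

test_that("truth categories partition planted variants as requested", {
  b <- simulate_cohort(small_cohort_spec(103), dir = tempfile())
  expect_true(all(b$truth$category %in%
                    c("inherited", "denovo_pass", "offtarget_coincident",
                      paste0("distractor:",
                             c("site_hard_snv", "site_hard_indel", "mask",
                               "genotype", "min_depth", "excess_depth",
                               "allele_fraction", "near_indel",
                               "sv_overlap", "complex_su")))))
  dis <- b$truth[startsWith(b$truth$category, "distractor:"), ]
  n_off <- sum(b$pedigree$role == "offspring")
  expect_equal(unname(table(dis$category)), rep(n_off, 10),
               ignore_attr = TRUE)
  # one of each category per offspring
  expect_true(all(table(dis$sample, dis$category) == 1))
  # no duplicated small-variant keys
  small <- b$truth[b$truth$vtype != "complex", ]
  expect_equal(anyDuplicated(small_key(small[, c("sample", "chrom", "pos",
                                                 "ref", "alt")])), 0L)
})

test_that("inherited offspring alleles exist in the designated parent", {
  b <- simulate_cohort(small_cohort_spec(104), dir = tempfile())
  vs <- read_multisample_vcf(b$paths[["vcf"]])
  ped <- b$pedigree
  inh <- b$truth[b$truth$category == "inherited", ]
  vk <- variant_key(vs$variants)
  m <- match(paste(inh$chrom, inh$pos, inh$ref, inh$alt, sep = ":"), vk)
  expect_false(anyNA(m))
  for (i in seq_len(nrow(inh))) {
    par_ids <- unlist(ped[ped$sample_id == inh$sample[i],
                          c("sire_id", "dam_id")])
    par_gt <- vs$gt[m[i], stats::na.omit(par_ids)]
    expect_true(any(grepl("1", par_gt, fixed = TRUE)),
                label = paste("parental carrier for", small_key(inh[i, ])))
    # and the offspring itself carries the allele
    expect_true(grepl("1", vs$gt[m[i], inh$sample[i]], fixed = TRUE))
  }
})

test_that("distractors violate exactly their intended predicate", {
  b <- simulate_cohort(small_cohort_spec(105), dir = tempfile())
  vs <- read_multisample_vcf(b$paths[["vcf"]])
  mask <- read_intervals_bed(c(b$paths[["mask_repeats"]],
                               b$paths[["mask_blacklist"]]))
  cutoff <- excessive_depth_cutoff(b$spec$depth_mean)
  tr <- b$truth[startsWith(b$truth$category, "distractor:") &
                  b$truth$vtype != "complex", ]
  vk <- variant_key(vs$variants)
  m <- match(paste(tr$chrom, tr$pos, tr$ref, tr$alt, sep = ":"), vk)
  expect_false(anyNA(m))
  for (i in seq_len(nrow(tr))) {
    j <- m[i]; o <- tr$sample[i]
    masked <- overlaps_mask(vs$variants[j, , drop = FALSE], mask)
    dp <- unname(vs$dp[j, o]); ada <- vs$ad_alt[j, o]
    adr <- vs$ad_ref[j, o]
    af <- unname(ada / (adr + ada))
    gt <- unname(vs$gt[j, o])
    switch(sub("distractor:", "", tr$category[i]),
           site_hard_snv = expect_lt(vs$variants$QD[j], 2),
           site_hard_indel = expect_gt(vs$variants$FS[j], 200),
           mask = expect_true(masked),
           genotype = expect_equal(gt, "0/0"),
           min_depth = expect_lt(dp, 10),
           excess_depth = expect_gt(dp, cutoff),
           allele_fraction = expect_lt(af, 0.10),
           near_indel = {
             expect_false(masked)
             expect_true(gt %in% c("0/1", "1/1") && dp >= 10 &&
                           dp <= cutoff && af >= 0.10)
           },
           sv_overlap = expect_true(nchar(tr$ref[i]) > 1))
    if (!tr$category[i] %in% c("distractor:mask")) {
      expect_false(masked)
    }
  }
  # complex_su distractors carry SU below the threshold
  sv <- read_sv_vcf(b$paths[["sv_vcf"]])
  dcx <- b$truth[b$truth$category == "distractor:complex_su", ]
  mm <- match(paste(dcx$chrom, dcx$pos - 1L), paste(sv$records$chrom,
                                                    sv$records$start))
  expect_false(anyNA(mm))
  expect_true(all(sv$records$su[mm] < 5))
  expect_true(all(sv$records$qual[mm] >= 100))
})

test_that("planted BE4 spectrum matches the spec weights within multinomial error", {
  sp <- small_cohort_spec(106, snv_rate = c(control = 10, ABE = 10,
                                            BE4 = 200))
  b <- simulate_cohort(sp, dir = tempfile())
  be4 <- b$pedigree$sample_id[!is.na(b$pedigree$group) &
                                b$pedigree$group == "BE4"]
  snv <- b$truth[b$truth$vtype == "snv" & b$truth$sample %in% be4 &
                   b$truth$category %in% c("denovo_pass",
                                           "offtarget_coincident"), ]
  tab <- spectrum_table(snv, collapse = TRUE)
  props <- colSums(tab) / sum(tab)
  want <- c("C>A" = 0.10, "C>G" = 0.08, "C>T" = 0.60, "T>A" = 0.04,
            "T>C" = 0.13, "T>G" = 0.05)
  n <- sum(tab)
  for (k in names(want)) {
    se <- sqrt(want[[k]] * (1 - want[[k]]) / n)
    expect_lt(abs(props[[k]] - want[[k]]), 4.5 * se + 0.01)
  }
})

test_that("zero rates with no distractors give an empty de novo truth", {
  sp <- small_cohort_spec(107, snv_rate = c(control = 0, ABE = 0, BE4 = 0),
                          indel_rate = c(control = 0, ABE = 0, BE4 = 0),
                          complex_rate_be4 = 0, distractors = FALSE)
  b <- simulate_cohort(sp, dir = tempfile())
  expect_true(all(b$truth$category == "inherited"))
})

test_that("truth tables round-trip through write/read", {
  b <- simulate_cohort(small_cohort_spec(108), dir = tempfile())
  p <- tempfile(fileext = ".tsv")
  write_truth(b$truth, p)
  back <- read_truth(p)
  expect_equal(back, b$truth, ignore_attr = TRUE)
  # empty table: header-only file
  p0 <- tempfile(fileext = ".tsv")
  write_truth(b$truth[0, ], p0)
  expect_equal(length(readLines(p0)), 1)
  expect_equal(nrow(read_truth(p0)), 0)
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(snv_rate = c(control = -1, ABE = 1, BE4 = 1)),
               "rates")
  expect_error(cohort_spec(offtarget_fraction = 1.5), "offtarget_fraction")
  expect_error(cohort_spec(group_sizes = c(control = 0, ABE = 13, BE4 = 9)),
               "group sizes")
  w <- default_spectrum_weights(); w[1, 1] <- w[1, 1] + 0.1
  expect_error(cohort_spec(spectrum_weights = w), "summing to 1")
})
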