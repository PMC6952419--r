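# The filter primitives of the post-calling cascade.  Each operation is
# vectorized over variants/calls and returns per-record pass flags plus
# the names of the violated conditions, so the cascade can assemble a
# complete decision trace.

#' Configuration of the de novo filtering cascade
#'
#' Houses every numeric threshold of the cascade.  Defaults reproduce the
#' standard GATK-style hard filters for jointly genotyped germline calls
#' plus the sample-level depth and allele-fraction cutoffs used for trio
#' de novo discovery at ~60X coverage.
#'
#' @param d average read depth per sample (reads); drives the
#'   excess-depth cutoff `d + 3*sqrt(d)`.
#' @param dp_min minimum per-sample read depth.
#' @param af_min minimum allele fraction `ad_alt / (ad_ref + ad_alt)`
#'   (applied to SNVs).
#' @param indel_window SNVs within this many bases (inclusive) of an indel
#'   border are removed as likely false positives.
#' @param sv_qual_min minimum QUAL for complex (SV-caller) indels.
#' @param sv_su_min minimum SU (pieces of supporting evidence across
#'   samples) for complex indels.
#' @param snv_hard named list of SNV site-annotation thresholds:
#'   `QD_min`, `FS_max`, `MQ_min`, `MQRankSum_min`, `ReadPosRankSum_min`,
#'   `SOR_max`.  A record fails when a *present* annotation violates its
#'   threshold (strict inequalities); absent annotations never fail.
#' @param indel_hard named list of simple-indel thresholds: `QD_min`,
#'   `FS_max`, `ReadPosRankSum_min`, `SOR_max`.
#' @return an object of class `"filter_config"`.
#' @examples
#' cfg <- filter_config(d = 60)
#' excessive_depth_cutoff(cfg$d)
#' @export
filter_config <- function(d = 60,
                          dp_min = 10,
                          af_min = 0.10,
                          indel_window = 5,
                          sv_qual_min = 100,
                          sv_su_min = 5,
                          snv_hard = list(QD_min = 2.0, FS_max = 60.0,
                                          MQ_min = 40.0, MQRankSum_min = -12.5,
                                          ReadPosRankSum_min = -8.0,
                                          SOR_max = 3.0),
                          indel_hard = list(QD_min = 2.0, FS_max = 200.0,
                                            ReadPosRankSum_min = -20.0,
                                            SOR_max = 10.0)) {
  cfg <- list(d = d, dp_min = dp_min, af_min = af_min,
              indel_window = indel_window, sv_qual_min = sv_qual_min,
              sv_su_min = sv_su_min, snv_hard = snv_hard,
              indel_hard = indel_hard)
  vals <- c(d, dp_min, af_min, indel_window, sv_qual_min, sv_su_min,
            unlist(snv_hard), unlist(indel_hard))
  if (any(!is.finite(vals))) stop("all filter thresholds must be finite")
  if (d <= 0) stop("average read depth d must be > 0")
  if (indel_window < 0) stop("indel_window must be >= 0")
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("De novo filter configuration\n")
  cat(sprintf("  depth: d = %g (excess-depth cutoff %.3f), dp_min = %g\n",
              x$d, excessive_depth_cutoff(x$d), x$dp_min))
  cat(sprintf("  allele fraction >= %g; SNV-near-indel window +/- %g bp\n",
              x$af_min, x$indel_window))
  cat("  SNV hard filters:  ",
      paste(names(x$snv_hard), unlist(x$snv_hard), sep = "=",
            collapse = ", "), "\n")
  cat("  indel hard filters:",
      paste(names(x$indel_hard), unlist(x$indel_hard), sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("  complex indels: QUAL >= %g, SU >= %g\n",
              x$sv_qual_min, x$sv_su_min))
  invisible(x)
}

#' Excess read-depth cutoff
#'
#' Calls whose depth exceeds `d + 3*sqrt(d)`, where `d` is the average
#' read depth, are removed as likely collapsed-repeat artifacts.
#'
#' @param d average read depth (> 0).
#' @return the numeric cutoff; depths strictly greater than it fail the
#'   excess-depth filter.
#' @examples
#' excessive_depth_cutoff(100)  # 130
#' @export
excessive_depth_cutoff <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0) {
    stop("average read depth d must be a single finite value > 0")
  }
  d + 3 * sqrt(d)
}

# evaluate one "annotation vs threshold" predicate; NA (absent) passes
viol <- function(x, thr, lower) {
  if (lower) !is.na(x) & x < thr else !is.na(x) & x > thr
}

hard_filter_eval <- function(variants, rules) {
  n <- nrow(variants)
  fails <- list()
  for (nm in names(rules)) {
    key <- sub("_(min|max)$", "", nm)
    lower <- grepl("_min$", nm)
    fails[[key]] <- viol(variants[[key]], rules[[nm]], lower)
  }
  fail_mat <- do.call(cbind, fails)
  reasons <- apply(fail_mat, 1, function(f)
    paste(colnames(fail_mat)[f], collapse = ","))
  list(pass = rowSums(fail_mat) == 0, reasons = reasons)
}

#' Site-level hard filters for SNVs
#'
#' A record fails when any *present* annotation violates
#' `QD < QD_min || FS > FS_max || MQ < MQ_min || MQRankSum < MQRankSum_min
#' || ReadPosRankSum < ReadPosRankSum_min || SOR > SOR_max` (all strict).
#' Absent annotations never fail: the caller omits rank-sum annotations at
#' homozygous sites, and failing those would discard most 1/1 calls.
#'
#' @param variants a [variant_set()] or its `variants` data.frame (rows
#'   should be SNVs).
#' @param cfg a [filter_config()].
#' @return list with `pass` (logical vector) and `reasons` (comma-joined
#'   names of the violated annotations, `""` when passing).
#' @export
apply_snv_hard_filters <- function(variants, cfg = filter_config()) {
  va <- if (inherits(variants, "variant_set")) variants$variants else variants
  hard_filter_eval(va, cfg$snv_hard)
}

#' Site-level hard filters for simple indels
#'
#' As [apply_snv_hard_filters()] but with the indel thresholds
#' (`QD`, `FS`, `ReadPosRankSum`, `SOR`).
#'
#' @inheritParams apply_snv_hard_filters
#' @return list with `pass` and `reasons`.
#' @export
apply_indel_hard_filters <- function(variants, cfg = filter_config()) {
  va <- if (inherits(variants, "variant_set")) variants$variants else variants
  hard_filter_eval(va, cfg$indel_hard)
}

#' Per-sample genotype / depth / allele-fraction filter
#'
#' A call passes when its genotype is 0/1 or 1/1, its depth is at least
#' `dp_min` and at most the excess-depth cutoff, and (for SNVs) its allele
#' fraction `ad_alt / (ad_ref + ad_alt)` is at least `af_min`.  An
#' unevaluable allele fraction (missing AD) fails the AF condition, and an
#' unevaluable depth fails the minimum-depth condition: a call whose
#' evidence cannot be assessed is not allowed through.
#'
#' @param gt character vector of genotypes (`"0/0"`, `"0/1"`, `"1/1"`,
#'   `NA` = missing).
#' @param ad_ref,ad_alt,dp integer vectors of allelic depths and total
#'   depth.
#' @param cfg a [filter_config()].
#' @param check_af apply the allele-fraction condition (used for SNVs;
#'   the simple-indel stream is filtered on genotype and depth only).
#' @return data.frame of per-condition pass flags (`genotype`,
#'   `min_depth`, `excess_depth`, `allele_fraction`) plus overall `pass`.
#' @export
sample_level_filter <- function(gt, ad_ref, ad_alt, dp,
                                cfg = filter_config(), check_af = TRUE) {
  cutoff <- excessive_depth_cutoff(cfg$d)
  genotype <- !is.na(gt) & gt %in% c("0/1", "1/1")
  min_depth <- !is.na(dp) & dp >= cfg$dp_min
  excess_depth <- is.na(dp) | dp <= cutoff
  denom <- ad_ref + ad_alt
  af <- ifelse(!is.na(denom) & denom > 0, ad_alt / denom, NA_real_)
  allele_fraction <- if (check_af) !is.na(af) & af >= cfg$af_min else
    rep(TRUE, length(gt))
  data.frame(genotype = genotype, min_depth = min_depth,
             excess_depth = excess_depth, allele_fraction = allele_fraction,
             pass = genotype & min_depth & excess_depth & allele_fraction)
}

# 1-based border positions of an indel: for a deletion the first and last
# REF base; for an insertion the two flanking REF positions pos, pos + 1.
indel_borders <- function(pos, ref, alt) {
  del <- nchar(ref) > nchar(alt)
  b1 <- pos
  b2 <- ifelse(del, pos + nchar(ref) - 1L, pos + 1L)
  cbind(b1, b2)
}

#' Remove SNVs near indel borders
#'
#' SNVs within `indel_window` bases (inclusive distance) of either border
#' of a same-chromosome indel are removed as likely alignment artifacts.
#' Borders: for a deletion, the first and last deleted REF base; for an
#' insertion, the two flanking reference positions.
#'
#' @param snvs data.frame of SNVs (`chrom`, `pos`, `ref`, `alt`).
#' @param indels data.frame of indels from the same sample's post-filter
#'   stream (`chrom`, `pos`, `ref`, `alt`).
#' @param cfg a [filter_config()].
#' @return logical vector: `TRUE` for SNVs to keep.
#' @export
remove_near_indel <- function(snvs, indels, cfg = filter_config()) {
  if (nrow(snvs) == 0) return(logical(0))
  if (nrow(indels) == 0) return(rep(TRUE, nrow(snvs)))
  b <- indel_borders(indels$pos, indels$ref, indels$alt)
  w <- cfg$indel_window
  windows <- GenomicRanges::GRanges(
    rep(indels$chrom, 2),
    IRanges::IRanges(start = pmax(1L, c(b[, 1], b[, 2]) - w),
                     end = c(b[, 1], b[, 2]) + w))
  snv_pos <- GenomicRanges::GRanges(snvs$chrom,
                                    IRanges::IRanges(snvs$pos, snvs$pos))
  !overlap_any(snv_pos, windows)
}

#' Filter complex (SV-caller) indels for one sample
#'
#' Keeps a record when the sample's genotype is 0/1 or 1/1, QUAL is at
#' least `sv_qual_min`, the sample's read coverage does not exceed the
#' excess-depth cutoff, SU (supporting evidence across samples) is at
#' least `sv_su_min`, and the interval does not overlap the genome mask.
#' A missing coverage value fails the coverage condition.
#'
#' @param sv an `"sv_set"` from [read_sv_vcf()].
#' @param sample sample name to evaluate.
#' @param cfg a [filter_config()].
#' @param mask genome mask [GenomicRanges::GRanges] or `NULL`.
#' @return data.frame of per-condition pass flags (`genotype`, `quality`,
#'   `coverage`, `su`, `mask`) plus overall `pass`.
#' @export
filter_complex_indels <- function(sv, sample, cfg = filter_config(),
                                  mask = NULL) {
  if (!sample %in% sv$samples) stop("unknown sample in SV set: ", sample)
  r <- sv$records
  gt <- sv$gt[, sample]
  dp <- sv$dp[, sample]
  cutoff <- excessive_depth_cutoff(cfg$d)
  genotype <- !is.na(gt) & gt %in% c("0/1", "1/1")
  quality <- !is.na(r$qual) & r$qual >= cfg$sv_qual_min
  coverage <- !is.na(dp) & dp <= cutoff
  su <- !is.na(r$su) & r$su >= cfg$sv_su_min
  mask_ok <- if (is.null(mask) || nrow(r) == 0) rep(TRUE, nrow(r)) else
    !overlap_any(gr_from_bed0(r$chrom, r$start, r$end), mask)
  data.frame(genotype = genotype, quality = quality, coverage = coverage,
             su = su, mask = mask_ok,
             pass = genotype & quality & coverage & su & mask_ok)
}

#' Exclude simple indels overlapping complex indels
#'
#' A simple indel is removed when its reference span intersects any
#' complex-indel interval identified in the same sample (half-open
#' intervals; abutting without shared bases is not an overlap).
#'
#' @param simple data.frame of simple indels (`chrom`, `pos`, `ref`).
#' @param complex data.frame of complex-indel intervals (`chrom`, `start`,
#'   `end`, half-open 0-based).
#' @return logical vector: `TRUE` for simple indels to keep.
#' @export
exclude_sv_overlapping_simple_indels <- function(simple, complex) {
  if (nrow(simple) == 0) return(logical(0))
  if (is.null(complex) || nrow(complex) == 0) return(rep(TRUE, nrow(simple)))
  !overlap_any(variant_span(simple),
               gr_from_bed0(complex$chrom, complex$start, complex$end))
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Subtract parental variation from an offspring variant set
#'
#' A variant is retained as de novo only when neither parent carries the
#' same alternate allele at the same site (exact match on chrom, pos, ref,
#' alt; any parental genotype containing allele 1 counts as carrying).  A
#' parent with a different alternate allele at the same position does not
#' exclude the child's variant.  Missing parental genotypes do not exclude
#' either; the cascade flags those as `parent_uncalled` in the trace.
#'
#' @param offspring data.frame of the offspring's candidate variants
#'   (`chrom`, `pos`, `ref`, `alt`).
#' @param sire,dam data.frames of variants carried by each parent
#'   (same columns); `NULL` for an unknown parent.
#' @return logical vector: `TRUE` for variants retained as de novo.
#' @export
subtract_parental <- function(offspring, sire, dam) {
  parent_keys <- c(if (!is.null(sire) && nrow(sire)) variant_key(sire),
                   if (!is.null(dam) && nrow(dam)) variant_key(dam))
  if (length(parent_keys) == 0) return(rep(TRUE, nrow(offspring)))
  !(variant_key(offspring) %in% parent_keys)
}
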