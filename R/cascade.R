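# The staged post-calling cascade: site-level hard filters -> mask
# exclusion -> per-sample genotype/depth/AF filters -> SNV-near-indel
# removal -> simple-vs-complex indel exclusion -> complex-indel filtering
# -> parental subtraction.  Every evaluated (variant, offspring) pair gets
# one trace row recording each stage's outcome in cascade order.

SMALL_STAGES <- c("site_hard", "mask", "genotype", "min_depth",
                  "excess_depth", "allele_fraction", "near_indel",
                  "sv_overlap", "parental")

pf <- function(x) ifelse(is.na(x), NA_character_, ifelse(x, "pass", "fail"))

first_fail_of <- function(stage_df, order) {
  ff <- rep(NA_character_, nrow(stage_df))
  for (col in order) {
    x <- stage_df[[col]]
    idx <- is.na(ff) & !is.na(x) & !x
    ff[idx] <- col
  }
  ff
}

#' Call de novo variants for every offspring of a trio cohort
#'
#' Runs the complete filtering cascade on jointly genotyped multi-sample
#' calls and subtracts parental variation, yielding per-offspring de novo
#' SNV, simple-indel and complex-indel sets together with a per-variant,
#' per-sample filter decision trace.
#'
#' Stages, in order: (1) site-level hard filters (class-specific
#' thresholds); (2) repeat/blacklist mask exclusion; (3) per-sample
#' genotype, minimum-depth, excess-depth and (SNVs only) allele-fraction
#' filters; (4) removal of SNVs within `indel_window` bp of a surviving
#' same-sample indel border; (5) exclusion of simple indels overlapping a
#' complex indel carried by the same sample; (6) complex-indel filtering
#' (genotype, QUAL, coverage, SU, mask); (7) parental subtraction.  Later
#' stages are only evaluated for survivors of earlier ones; a trace entry
#' of `NA` means the stage was not reached.
#'
#' @param vs a [variant_set()] containing parents and offspring.
#' @param sv optional `"sv_set"` of complex indels from [read_sv_vcf()].
#' @param mask genome mask from [read_intervals_bed()], or `NULL`.
#' @param pedigree a [pedigree_cohort()]; every named parent of an
#'   offspring must be present among the VCF samples.
#' @param cfg a [filter_config()].
#' @return an object of class `"denovo_cohort"`: a list with data.frames
#'   `snvs`, `indels`, `complex` (passing de novo calls, one row per
#'   variant and sample), `trace` and `sv_trace` (full decision traces),
#'   `stage_counts` (per-sample survivor funnel), plus the offspring ids,
#'   pedigree and configuration used.
#' @export
call_denovo_cohort <- function(vs, sv = NULL, mask = NULL, pedigree,
                               cfg = filter_config()) {
  stopifnot(inherits(vs, "variant_set"))
  pedigree <- pedigree_cohort(as.data.frame(pedigree))
  off <- pedigree[pedigree$role == "offspring", , drop = FALSE]
  if (nrow(off) == 0) stop("pedigree contains no offspring")
  for (i in seq_len(nrow(off))) {
    par_i <- stats::na.omit(c(off$sire_id[i], off$dam_id[i]))
    missing <- setdiff(par_i, vs$samples)
    if (length(missing)) {
      stop("offspring ", off$sample_id[i],
           ": parent sample(s) not in the VCF: ",
           paste(missing, collapse = ", "))
    }
    if (!off$sample_id[i] %in% vs$samples) {
      stop("offspring sample not in the VCF: ", off$sample_id[i])
    }
  }

  va <- vs$variants
  n <- nrow(va)
  is_snv <- va$vclass == "SNV"
  site_pass <- logical(n)
  site_reason <- character(n)
  if (any(is_snv)) {
    h <- apply_snv_hard_filters(va[is_snv, , drop = FALSE], cfg)
    site_pass[is_snv] <- h$pass
    site_reason[is_snv] <- h$reasons
  }
  if (any(!is_snv)) {
    h <- apply_indel_hard_filters(va[!is_snv, , drop = FALSE], cfg)
    site_pass[!is_snv] <- h$pass
    site_reason[!is_snv] <- h$reasons
  }
  mask_pass <- !overlaps_mask(va, mask)

  trace_list <- list()
  sv_trace_list <- list()
  snv_list <- list()
  indel_list <- list()
  complex_list <- list()
  counts_list <- list()

  for (i in seq_len(nrow(off))) {
    sample <- off$sample_id[i]
    sire <- off$sire_id[i]
    dam <- off$dam_id[i]
    gt <- vs$gt[, sample]
    ad_ref <- vs$ad_ref[, sample]
    ad_alt <- vs$ad_alt[, sample]
    dp <- vs$dp[, sample]

    sampf <- sample_level_filter(gt, ad_ref, ad_alt, dp, cfg,
                                 check_af = TRUE)
    # the AF condition applies to the SNV stream only
    sampf$allele_fraction[!is_snv] <- TRUE
    sampf$pass <- sampf$genotype & sampf$min_depth & sampf$excess_depth &
      sampf$allele_fraction

    alive <- site_pass & mask_pass & sampf$pass

    # stage 4: SNVs near surviving same-sample indel borders
    near_indel <- rep(NA, n)
    surv_indel <- which(alive & !is_snv)
    surv_snv <- which(alive & is_snv)
    if (length(surv_snv)) {
      keep <- remove_near_indel(va[surv_snv, , drop = FALSE],
                                va[surv_indel, , drop = FALSE], cfg)
      near_indel[surv_snv] <- keep
      alive[surv_snv] <- keep
    }

    # stage 5: simple indels overlapping complex indels carried by sample
    sv_overlap <- rep(NA, n)
    carried_sv <- NULL
    if (!is.null(sv) && nrow(sv$records) > 0) {
      sv_gt <- sv$gt[, sample]
      carried_sv <- sv$records[!is.na(sv_gt) & grepl("1", sv_gt, fixed = TRUE),
                               , drop = FALSE]
    }
    surv_indel <- which(alive & !is_snv)
    if (length(surv_indel)) {
      keep <- exclude_sv_overlapping_simple_indels(
        va[surv_indel, , drop = FALSE], carried_sv)
      sv_overlap[surv_indel] <- keep
      alive[surv_indel] <- keep
    }

    # stage 7: parental subtraction (allele-level exact match)
    carries <- rep(FALSE, n)
    uncalled <- rep(FALSE, n)
    for (p in stats::na.omit(c(sire, dam))) {
      pgt <- vs$gt[, p]
      carries <- carries | (!is.na(pgt) & grepl("1", pgt, fixed = TRUE))
      uncalled <- uncalled | is.na(pgt)
    }
    parental <- rep(NA, n)
    surv <- which(alive)
    parental[surv] <- !carries[surv]
    alive[surv] <- !carries[surv]

    af <- ifelse(!is.na(ad_ref + ad_alt) & (ad_ref + ad_alt) > 0,
                 ad_alt / (ad_ref + ad_alt), NA_real_)
    stage_df <- data.frame(
      site_hard = site_pass, mask = mask_pass,
      genotype = sampf$genotype, min_depth = sampf$min_depth,
      excess_depth = sampf$excess_depth,
      allele_fraction = ifelse(is_snv, sampf$allele_fraction, NA),
      near_indel = near_indel, sv_overlap = sv_overlap,
      parental = parental)
    trace <- data.frame(
      sample = rep(sample, n), chrom = va$chrom, pos = va$pos,
      ref = va$ref, alt = va$alt, vclass = va$vclass,
      stringsAsFactors = FALSE)
    for (s in SMALL_STAGES) trace[[s]] <- pf(stage_df[[s]])
    trace$site_hard_reason <- site_reason
    trace$parent_uncalled <- uncalled
    trace$status <- ifelse(alive, "pass", "fail")
    trace$first_fail <- first_fail_of(stage_df, SMALL_STAGES)
    trace_list[[sample]] <- trace

    pass_df <- data.frame(
      sample = rep(sample, sum(alive)),
      va[alive, c("chrom", "pos", "ref", "alt", "vclass"), drop = FALSE],
      gt = gt[alive], ad_ref = ad_ref[alive], ad_alt = ad_alt[alive],
      dp = dp[alive], af = af[alive],
      parent_uncalled = uncalled[alive],
      stringsAsFactors = FALSE, row.names = NULL)
    snv_list[[sample]] <- pass_df[pass_df$vclass == "SNV", , drop = FALSE]
    indel_list[[sample]] <- pass_df[pass_df$vclass != "SNV", , drop = FALSE]

    # complex indels for this sample
    if (!is.null(sv) && nrow(sv$records) > 0) {
      cx <- filter_complex_indels(sv, sample, cfg, mask)
      svt <- data.frame(sample = sample, sv$records,
                        stringsAsFactors = FALSE)
      for (s in c("genotype", "quality", "coverage", "su", "mask")) {
        svt[[s]] <- pf(cx[[s]])
      }
      svt$status <- ifelse(cx$pass, "pass", "fail")
      svt$first_fail <- first_fail_of(
        cx[, c("genotype", "quality", "coverage", "su", "mask")],
        c("genotype", "quality", "coverage", "su", "mask"))
      sv_trace_list[[sample]] <- svt
      complex_list[[sample]] <- data.frame(
        sample = rep(sample, sum(cx$pass)),
        sv$records[cx$pass, , drop = FALSE],
        stringsAsFactors = FALSE, row.names = NULL)
    }

    counts_list[[sample]] <- data.frame(
      sample = sample,
      candidates = n,
      site_hard = sum(site_pass),
      mask = sum(site_pass & mask_pass),
      sample_filters = sum(site_pass & mask_pass & sampf$pass),
      near_indel = sum(site_pass & mask_pass & sampf$pass &
                         (is.na(near_indel) | near_indel)),
      sv_overlap = sum(site_pass & mask_pass & sampf$pass &
                         (is.na(near_indel) | near_indel) &
                         (is.na(sv_overlap) | sv_overlap)),
      denovo = sum(alive),
      stringsAsFactors = FALSE)
  }

  res <- list(
    snvs = do.call(rbind, c(snv_list, list(make.row.names = FALSE))),
    indels = do.call(rbind, c(indel_list, list(make.row.names = FALSE))),
    complex = if (length(complex_list))
      do.call(rbind, c(complex_list, list(make.row.names = FALSE))) else
        data.frame(sample = character(0), chrom = character(0),
                   start = integer(0), end = integer(0),
                   svtype = character(0), qual = numeric(0),
                   su = integer(0)),
    trace = do.call(rbind, c(trace_list, list(make.row.names = FALSE))),
    sv_trace = if (length(sv_trace_list))
      do.call(rbind, c(sv_trace_list, list(make.row.names = FALSE))) else NULL,
    stage_counts = do.call(rbind, c(counts_list, list(make.row.names = FALSE))),
    offspring = off$sample_id,
    pedigree = pedigree,
    config = cfg)
  class(res) <- "denovo_cohort"
  res
}

#' Per-offspring de novo variant counts
#'
#' @param cohort a `"denovo_cohort"` from [call_denovo_cohort()].
#' @return data.frame with one row per offspring: `sample`, `group`,
#'   `n_snv`, `n_indel`, `n_complex`.
#' @export
denovo_counts <- function(cohort) {
  stopifnot(inherits(cohort, "denovo_cohort"))
  ped <- cohort$pedigree
  samples <- cohort$offspring
  cnt <- function(df) {
    tab <- table(factor(df$sample, levels = samples))
    as.integer(tab)
  }
  data.frame(sample = samples,
             group = ped$group[match(samples, ped$sample_id)],
             n_snv = cnt(cohort$snvs),
             n_indel = cnt(cohort$indels),
             n_complex = cnt(cohort$complex),
             stringsAsFactors = FALSE)
}

#' @export
print.denovo_cohort <- function(x, ...) {
  cnt <- denovo_counts(x)
  cat("De novo callset:", length(x$offspring), "offspring\n")
  cat(sprintf("  passing: %d SNVs, %d simple indels, %d complex indels\n",
              nrow(x$snvs), nrow(x$indels), nrow(x$complex)))
  agg <- stats::aggregate(n_snv ~ group, cnt, mean)
  cat("  mean de novo SNVs per mouse by group:\n")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("    %-8s %.1f\n", agg$group[i], agg$n_snv[i]))
  }
  invisible(x)
}

#' @export
summary.denovo_cohort <- function(object, ...) {
  cnt <- denovo_counts(object)
  out <- list(counts = cnt,
              funnel = object$stage_counts)
  class(out) <- "summary.denovo_cohort"
  out
}

#' @export
print.summary.denovo_cohort <- function(x, ...) {
  cat("Per-sample de novo counts:\n")
  print(x$counts, row.names = FALSE)
  cat("\nFilter funnel (survivors per stage):\n")
  print(x$funnel, row.names = FALSE)
  invisible(x)
}
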