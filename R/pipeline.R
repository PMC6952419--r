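# End-to-end orchestration: read inputs, run the cascade, tabulate
# spectra, compare groups, assess off-target coincidence, and write a
# report bundle.

#' Run the complete de novo / off-target burden pipeline
#'
#' Reads the multi-sample VCF, optional complex-indel VCF, mask BED files,
#' pedigree and optional predicted off-target site table; runs
#' [call_denovo_cohort()]; tabulates per-sample counts and mutational
#' spectra; compares groups ([summarize_groups()] for SNVs and indels);
#' and, when an off-target table is given, applies [filter_sites()],
#' [population_recurrence_filter()] and [coincidence()].  With `out_dir`
#' set, writes per-sample de novo VCFs, the decision trace, count and
#' spectrum matrices, a statistics JSON, the coincidence report, a
#' human-readable summary and a configuration echo sufficient to
#' reproduce the run.
#'
#' @param vcf path to the multi-sample small-variant VCF.
#' @param pedigree path to the pedigree table, or a [pedigree_cohort()].
#' @param mask_beds character vector of BED paths (unioned); `NULL` for
#'   no masking.
#' @param sv_vcf optional path to the complex-indel (SV) VCF.
#' @param offtargets optional path to the predicted off-target site table.
#' @param config a [filter_config()].
#' @param out_dir optional output directory for the report bundle.
#' @return an object of class `"denovo_report"`: list with `callset`
#'   (the `"denovo_cohort"`), `counts`, `spectrum` and
#'   `spectrum_collapsed` matrices, `comparison_snv`, `comparison_indel`,
#'   `coincidence` (or `NULL`), `config` and `inputs`.
#' @export
run_denovo_pipeline <- function(vcf, pedigree, mask_beds = NULL,
                                sv_vcf = NULL, offtargets = NULL,
                                config = filter_config(),
                                out_dir = NULL) {
  for (p in c(vcf, sv_vcf, mask_beds, offtargets)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  vs <- read_multisample_vcf(vcf)
  ped <- if (inherits(pedigree, "pedigree_cohort")) pedigree else
    read_pedigree(pedigree)
  unmatched <- setdiff(ped$sample_id, vs$samples)
  if (length(unmatched)) {
    stop("pedigree samples missing from the VCF: ",
         paste(unmatched, collapse = ", "))
  }
  mask <- if (!is.null(mask_beds)) read_intervals_bed(mask_beds) else NULL
  sv <- if (!is.null(sv_vcf)) read_sv_vcf(sv_vcf) else NULL

  callset <- call_denovo_cohort(vs, sv = sv, mask = mask, pedigree = ped,
                                cfg = config)
  counts <- denovo_counts(callset)
  spec_dir <- spectrum_table(callset$snvs, samples = callset$offspring)
  spec_col <- spectrum_table(callset$snvs, samples = callset$offspring,
                             collapse = TRUE)
  comparison_snv <- summarize_groups(counts, what = "snv")
  comparison_indel <- summarize_groups(counts, what = "indel")

  coin <- NULL
  if (!is.null(offtargets)) {
    sites <- read_offtarget_sites(offtargets)
    sites_kept <- filter_sites(sites, mask)
    candidates <- population_recurrence_filter(callset$snvs, ped)
    coin <- coincidence(candidates, sites_kept)
    coin$n_sites <- nrow(sites)
    coin$n_sites_retained <- nrow(sites_kept)
    coin$n_recurrent_excluded <- nrow(attr(candidates, "excluded"))
  }

  report <- structure(
    list(callset = callset, counts = counts, spectrum = spec_dir,
         spectrum_collapsed = spec_col, comparison_snv = comparison_snv,
         comparison_indel = comparison_indel, coincidence = coin,
         config = config,
         inputs = list(vcf = vcf, sv_vcf = sv_vcf, mask_beds = mask_beds,
                       pedigree = if (is.character(pedigree)) pedigree else
                         "<in-memory>", offtargets = offtargets)),
    class = "denovo_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' @param report a `"denovo_report"` from [run_denovo_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "denovo_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cs <- report$callset

  # per-sample de novo VCFs
  small <- rbind(cs$snvs, cs$indels)
  for (s in cs$offspring) {
    sub <- small[small$sample == s, , drop = FALSE]
    sub <- sub[order(factor(sub$chrom), sub$pos), , drop = FALSE]
    n <- nrow(sub)
    vs1 <- variant_set(sub[, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                       matrix(sub$gt, n, 1), matrix(sub$ad_ref, n, 1),
                       matrix(sub$ad_alt, n, 1), matrix(sub$dp, n, 1), s)
    write_variant_vcf(vs1, file.path(out_dir,
                                     sprintf("denovo_%s.vcf", s)))
  }

  utils::write.table(cs$trace, file.path(out_dir, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cs$sv_trace)) {
    utils::write.table(cs$sv_trace, file.path(out_dir, "sv_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$counts, file.path(out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cs$stage_counts, file.path(out_dir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = rownames(report$spectrum),
                                report$spectrum, check.names = FALSE),
                     file.path(out_dir, "spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  stats_json <- list(
    snv = comparison_as_list(report$comparison_snv),
    indel = comparison_as_list(report$comparison_indel))
  if (!is.null(report$coincidence)) {
    co <- report$coincidence
    stats_json$coincidence <- list(
      n_denovo = co$n_denovo, n_coincident = co$n_coincident,
      fraction = co$fraction, n_sites = co$n_sites,
      n_sites_retained = co$n_sites_retained,
      n_recurrent_excluded = co$n_recurrent_excluded)
    if (nrow(co$matched)) {
      utils::write.table(co$matched, file.path(out_dir, "coincidence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  cfg <- report$config
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))

  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con)
  print(cs)
  print(report$comparison_snv)
  print(report$comparison_indel)
  if (!is.null(report$coincidence)) print(report$coincidence)
  sink()
  close(con)
  invisible(out_dir)
}

comparison_as_list <- function(cmp) {
  out <- list(groups = cmp$stats)
  if (!is.null(cmp$kruskal)) {
    out$kruskal_wallis <- list(H = unname(cmp$kruskal$statistic),
                               p = cmp$kruskal$p.value)
    out$pairwise <- cmp$pairwise
  }
  out
}

#' @export
print.denovo_report <- function(x, ...) {
  print(x$callset)
  print(x$comparison_snv)
  print(x$comparison_indel)
  if (!is.null(x$coincidence)) print(x$coincidence)
  invisible(x)
}
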