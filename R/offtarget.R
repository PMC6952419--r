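# Coincidence of de novo SNVs with predicted sgRNA off-target sites.

#' Mask-filter predicted off-target sites
#'
#' Removes sites whose interval overlaps the genome mask (the same
#' repeat/blacklist criteria applied to variants), so coincidence is only
#' assessed in analyzable regions.
#'
#' @param sites an `"offtarget_sites"` data.frame from
#'   [read_offtarget_sites()].
#' @param mask genome mask [GenomicRanges::GRanges] or `NULL`.
#' @return the retained subset of `sites`.
#' @export
filter_sites <- function(sites, mask) {
  if (is.null(mask) || nrow(sites) == 0) return(sites)
  keep <- !overlap_any(sites_gr(sites), mask)
  sites[keep, , drop = FALSE]
}

#' Exclude population-recurrent variants from off-target accounting
#'
#' A candidate variant (chrom, pos, ref, alt) observed in at least one
#' non-edited animal (a control offspring) cannot be a consequence of base
#' editing and is excluded from coincidence accounting for every sample.
#' Recurrence within the edited groups alone does not exclude.  Parents
#' need no explicit handling here: any variant they carry was already
#' removed by parental subtraction.
#'
#' @param candidates data.frame of per-sample de novo SNVs with columns
#'   `sample`, `chrom`, `pos`, `ref`, `alt`.
#' @param pedigree a [pedigree_cohort()] supplying group labels.
#' @return `candidates` with recurrent variants removed; the dropped rows
#'   are kept in attribute `"excluded"`.
#' @export
population_recurrence_filter <- function(candidates, pedigree) {
  pedigree <- pedigree_cohort(as.data.frame(pedigree))
  non_edited <- pedigree$sample_id[
    pedigree$role == "parent" |
      (!is.na(pedigree$group) & pedigree$group == "control")]
  keys <- variant_key(candidates)
  control_keys <- unique(keys[candidates$sample %in% non_edited])
  # a variant seen in any non-edited animal is excluded everywhere
  drop <- keys %in% control_keys
  out <- candidates[!drop, , drop = FALSE]
  attr(out, "excluded") <- candidates[drop, , drop = FALSE]
  out
}

#' Coincidence of de novo SNVs with predicted off-target sites
#'
#' Counts de novo SNVs whose position falls inside any retained site
#' interval (positional membership; alleles are not compared) and reports
#' the coincidence fraction.
#'
#' @param denovo data.frame of de novo SNVs (`chrom`, `pos`, 1-based;
#'   optionally `sample`).
#' @param sites retained `"offtarget_sites"` (after [filter_sites()]).
#' @return an object of class `"coincidence_result"`: list with
#'   `n_denovo`, `n_coincident`, `fraction` (`NA` when `n_denovo == 0`),
#'   and `matched` (data.frame pairing each coincident SNV with its site).
#' @export
coincidence <- function(denovo, sites) {
  n_denovo <- nrow(denovo)
  if (n_denovo == 0) {
    res <- list(n_denovo = 0L, n_coincident = 0L, fraction = NA_real_,
                matched = data.frame())
    class(res) <- "coincidence_result"
    return(res)
  }
  if (nrow(sites) == 0) {
    hits <- S4Vectors::DataFrame()
    n_coincident <- 0L
    matched <- data.frame()
  } else {
    q <- GenomicRanges::GRanges(denovo$chrom,
                                IRanges::IRanges(denovo$pos, denovo$pos))
    s <- sites_gr(sites)
    lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
    GenomeInfoDb::seqlevels(q) <- lv
    GenomeInfoDb::seqlevels(s) <- lv
    ov <- GenomicRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    n_coincident <- length(unique(qh))
    matched <- if (length(qh)) {
      cbind(denovo[qh, , drop = FALSE],
            site_chrom = sites$chrom[sh],
            site_start = sites$start[sh],
            site_end = sites$end[sh],
            site_mismatches = sites$mismatches[sh])
    } else data.frame()
  }
  res <- list(n_denovo = as.integer(n_denovo),
              n_coincident = as.integer(n_coincident),
              fraction = n_coincident / n_denovo,
              matched = matched)
  class(res) <- "coincidence_result"
  res
}

#' @export
print.coincidence_result <- function(x, ...) {
  if (x$n_denovo == 0) {
    cat("Off-target coincidence: no de novo SNVs to assess",
        "(fraction not available)\n")
  } else {
    cat(sprintf(
      "Off-target coincidence: %d / %d de novo SNVs inside predicted sites (%.3f%%)\n",
      x$n_coincident, x$n_denovo, 100 * x$fraction))
  }
  invisible(x)
}
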