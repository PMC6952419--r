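# Interval handling: genome masks (repeat + blacklist unions), BED io,
# and variant/interval overlap.  Internal convention: variants are VCF
# 1-based, BED files are half-open 0-based; every conversion between the
# two lives in this file.

# GRanges from half-open 0-based intervals
gr_from_bed0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(normalize_chrom(chrom),
                         IRanges::IRanges(start = start0 + 1L,
                                          end = end0))
}

# concatenate GRanges without seqinfo-merge warnings (empty operands
# carry no seqlevels)
gr_c <- function(...) suppressWarnings(c(...))

# overlap query that tolerates disjoint seqlevel sets
overlap_any <- function(query, subject) {
  if (length(subject) == 0 || length(query) == 0) {
    return(rep(FALSE, length(query)))
  }
  lv <- union(GenomeInfoDb::seqlevels(query), GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- lv
  GenomeInfoDb::seqlevels(subject) <- lv
  IRanges::overlapsAny(query, subject)
}

#' Build a genome mask from BED interval files
#'
#' Reads one or more BED3+ files (half-open 0-based intervals, e.g. UCSC
#' masked repeats, simple repeats and ENCODE blacklist regions), takes
#' their union and merges overlapping intervals per chromosome.  Variants
#' and predicted off-target sites overlapping the mask are excluded by the
#' filtering cascade.
#'
#' @param paths character vector of BED file paths (all are unioned).
#' @return a merged, sorted [GenomicRanges::GRanges] (the genome mask).
#' @export
read_intervals_bed <- function(paths) {
  if (length(paths) == 0) stop("at least one BED path is required")
  grs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("BED file not found: ", p)
    lines <- readLines(p)
    keep <- nzchar(lines) & !startsWith(lines, "#") &
      !startsWith(lines, "track") & !startsWith(lines, "browser")
    if (!any(keep)) return(GenomicRanges::GRanges())
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    line_no <- which(keep)
    nf <- lengths(fields)
    if (any(nf < 3)) {
      stop("BED parse error at line ", line_no[which(nf < 3)[1]], " of ", p,
           ": fewer than 3 fields")
    }
    chrom <- vapply(fields, `[`, character(1), 1)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
    bad <- is.na(start0) | is.na(end0) | start0 >= end0 | start0 < 0
    if (any(bad)) {
      stop("BED parse error at line ", line_no[which(bad)[1]], " of ", p,
           ": invalid interval (requires 0 <= start < end)")
    }
    gr_from_bed0(chrom, start0, end0)
  })
  gr <- do.call(gr_c, grs)
  GenomicRanges::sort(GenomicRanges::reduce(gr))
}

#' Genomic span of variants as GRanges
#'
#' The reference-spanned bases of each variant: 1-based positions
#' `pos .. pos + nchar(ref) - 1`.
#' @param variants data.frame with `chrom`, `pos`, `ref`.
#' @return a [GenomicRanges::GRanges].
#' @keywords internal
variant_span <- function(variants) {
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(start = variants$pos,
                                          width = nchar(variants$ref)))
}

#' Does a variant overlap the genome mask?
#'
#' A variant overlaps when any of its reference-spanned bases intersects a
#' mask interval.  For an SNV that is the single base at `pos`; for a
#' deletion, the whole deleted REF span.
#'
#' @param variants a [variant_set()] or a data.frame with `chrom`, `pos`,
#'   `ref`.
#' @param mask a merged [GenomicRanges::GRanges] from [read_intervals_bed()],
#'   or `NULL` for no masking.
#' @return logical vector, one element per variant.
#' @export
overlaps_mask <- function(variants, mask) {
  va <- if (inherits(variants, "variant_set")) variants$variants else variants
  if (is.null(mask)) return(rep(FALSE, nrow(va)))
  overlap_any(variant_span(va), mask)
}

#' Read the pedigree/group table of a trio cohort
#'
#' Tab-separated with header columns `sample_id`, `role`
#' (`parent`/`offspring`), `group` (`control`/`ABE`/`BE4`, `.` for
#' parents), `sire_id`, `dam_id` (`.` when unknown).
#'
#' @param path path to the pedigree table.
#' @return a data.frame of class `"pedigree_cohort"`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  pedigree_cohort(df)
}

#' Construct and validate a pedigree cohort table
#'
#' @param df data.frame with columns `sample_id`, `role`, `group`,
#'   `sire_id`, `dam_id` (`"."` or `NA` for unset fields).
#' @return the validated data.frame, classed `"pedigree_cohort"`.
#' @export
pedigree_cohort <- function(df) {
  need <- c("sample_id", "role", "group", "sire_id", "dam_id")
  if (!all(need %in% names(df))) {
    stop("pedigree table must have columns: ", paste(need, collapse = ", "))
  }
  for (k in c("group", "sire_id", "dam_id")) {
    df[[k]][df[[k]] %in% c(".", "")] <- NA_character_
  }
  if (!all(df$role %in% c("parent", "offspring"))) {
    stop("pedigree role must be 'parent' or 'offspring'")
  }
  off <- df$role == "offspring"
  has_parent <- !is.na(df$sire_id) | !is.na(df$dam_id)
  if (any(off & !has_parent)) {
    stop("offspring without any resolvable parent id: ",
         paste(df$sample_id[off & !has_parent], collapse = ", "))
  }
  parent_ids <- df$sample_id[df$role == "parent"]
  refs <- stats::na.omit(unique(c(df$sire_id[off], df$dam_id[off])))
  if (!all(refs %in% parent_ids)) {
    stop("unknown parent id referenced: ",
         paste(setdiff(refs, parent_ids), collapse = ", "))
  }
  if (any(off & is.na(df$group))) {
    stop("every offspring must have a group label")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in pedigree")
  class(df) <- c("pedigree_cohort", "data.frame")
  df
}

#' Offspring sample ids of a pedigree
#' @param pedigree a [pedigree_cohort()].
#' @return character vector.
#' @export
offspring_ids <- function(pedigree) {
  pedigree$sample_id[pedigree$role == "offspring"]
}

#' Read a predicted off-target site table
#'
#' Tab-separated with header `chrom`, `start`, `end` (half-open 0-based
#' interval covering protospacer + PAM) and `mismatches` (mismatch count
#' versus the sgRNA).
#'
#' @param path path to the site table.
#' @return data.frame of class `"offtarget_sites"`.
#' @export
read_offtarget_sites <- function(path) {
  if (!file.exists(path)) stop("off-target site table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "mismatches")
  if (!all(need %in% names(df))) {
    stop("off-target table must have columns: ", paste(need, collapse = ", "))
  }
  df$chrom <- normalize_chrom(as.character(df$chrom))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$mismatches <- as.integer(df$mismatches)
  if (any(df$end <= df$start)) stop("off-target site with end <= start")
  if (any(df$mismatches < 0)) stop("negative mismatch count")
  class(df) <- c("offtarget_sites", "data.frame")
  df
}

sites_gr <- function(sites) gr_from_bed0(sites$chrom, sites$start, sites$end)
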