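# Synthetic trio-cohort generator.  Produces a complete input bundle
# (multi-sample VCF, SV VCF, mask BEDs, off-target site table, pedigree
# table) plus a machine-readable truth table, with the statistical
# structure the analysis assumes: Mendelian inheritance of parental
# variants, group-specific Poisson de novo SNV rates and spectra, a
# controlled fraction of de novo SNVs inside predicted off-target sites,
# and one "distractor" variant per filter category per offspring that is
# built to fail exactly that filter.

DISTRACTOR_CATEGORIES <- c("site_hard_snv", "site_hard_indel", "mask",
                           "genotype", "min_depth", "excess_depth",
                           "allele_fraction", "near_indel", "sv_overlap",
                           "complex_su")

#' Cascade filter targeted by a planted distractor category
#'
#' Maps a truth-table `distractor:<name>` category to the trace column
#' (stage name) that the variant is constructed to fail first.
#'
#' @param category character vector of truth categories.
#' @return character vector of stage names (`NA` for non-distractors).
#' @export
distractor_filter_name <- function(category) {
  map <- c("distractor:site_hard_snv" = "site_hard",
           "distractor:site_hard_indel" = "site_hard",
           "distractor:mask" = "mask",
           "distractor:genotype" = "genotype",
           "distractor:min_depth" = "min_depth",
           "distractor:excess_depth" = "excess_depth",
           "distractor:allele_fraction" = "allele_fraction",
           "distractor:near_indel" = "near_indel",
           "distractor:sv_overlap" = "sv_overlap",
           "distractor:complex_su" = "su")
  unname(map[category])
}

#' Default group-specific substitution spectrum weights
#'
#' Rows `control`, `ABE`, `BE4` over the 12 directional substitution
#' classes.  Control and ABE use a generic mammalian germline-like
#' background (C>T/T>C dominated); BE4 is strongly enriched for C>T with
#' minor C>A and C>G components, reflecting cytosine-deaminase activity.
#' Each collapsed class weight is split equally between its two strands.
#'
#' @return 3 x 12 numeric matrix, rows summing to 1.
#' @export
default_spectrum_weights <- function() {
  collapsed <- rbind(
    control = c("C>A" = 0.08, "C>G" = 0.07, "C>T" = 0.40,
                "T>A" = 0.07, "T>C" = 0.28, "T>G" = 0.10),
    ABE = c("C>A" = 0.08, "C>G" = 0.07, "C>T" = 0.40,
            "T>A" = 0.07, "T>C" = 0.28, "T>G" = 0.10),
    BE4 = c("C>A" = 0.10, "C>G" = 0.08, "C>T" = 0.60,
            "T>A" = 0.04, "T>C" = 0.13, "T>G" = 0.05))
  # directional class -> collapsed class
  to_collapsed <- vapply(strsplit(SUB_CLASSES, ">"), function(ra) {
    if (ra[1] %in% c("A", "G")) {
      paste0(COMPLEMENT[ra[1]], ">", COMPLEMENT[ra[2]])
    } else paste0(ra[1], ">", ra[2])
  }, character(1))
  w <- collapsed[, to_collapsed] / 2
  colnames(w) <- SUB_CLASSES
  w
}

#' Specification of a synthetic trio cohort
#'
#' Defines the study conditions emulated by [simulate_cohort()]: one sire
#' and eight dams, 13 control / 13 ABE / 9 BE4 offspring sequenced at an
#' average depth of 60X, per-group de novo SNV rates of 132 / 119 / 221
#' per mouse (Poisson), equal de novo indel rates across groups, a
#' BE4-specific C>T excess in the substitution spectrum, occasional
#' complex deletions in BE4 animals, and 2% of de novo SNVs placed inside
#' predicted off-target sites.
#'
#' @param seed integer seed; the bundle is deterministic given the spec
#'   and seed.
#' @param genome named vector of chromosome lengths (toy genome).
#' @param n_dams number of dams (a single sire is always generated).
#' @param group_sizes named integer vector (`control`, `ABE`, `BE4`).
#' @param snv_rate named per-group mean de novo SNV count per mouse.
#' @param indel_rate named per-group mean de novo simple-indel count.
#' @param spectrum_weights 3 x 12 matrix of substitution-class weights
#'   (rows `control`, `ABE`, `BE4`, rows sum to 1).
#' @param depth_mean mean per-call read depth (average coverage d).
#' @param offtarget_fraction fraction q of de novo SNVs placed inside
#'   retained predicted off-target sites.
#' @param n_offtarget_sites number of predicted off-target sites.
#' @param offtarget_masked_fraction fraction of sites placed inside the
#'   mask (these are removed by [filter_sites()] and never host variants).
#' @param mask_fraction fraction of the toy genome covered by the
#'   repeat/blacklist mask.
#' @param n_parental_snvs,n_parental_indels germline het variants per
#'   parent (inherited by offspring with probability 1/2 each).
#' @param mosaic_fraction fraction of edited-group de novo SNVs drawn
#'   with a mosaic-like allele fraction near 0.25 instead of 0.5.
#' @param complex_rate_be4 mean number of passing complex deletions per
#'   BE4 mouse.
#' @param distractors plant one distractor per filter category per
#'   offspring (see [distractor_filter_name()]).
#' @param dispersion per-mouse count dispersion: 1 = Poisson; values > 1
#'   use a negative binomial with variance `dispersion * mean`.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(seed = 1,
                        genome = c(chr1 = 10e6, chr2 = 10e6, chr3 = 10e6),
                        n_dams = 8,
                        group_sizes = c(control = 13, ABE = 13, BE4 = 9),
                        snv_rate = c(control = 132, ABE = 119, BE4 = 221),
                        indel_rate = c(control = 12, ABE = 12, BE4 = 12),
                        spectrum_weights = default_spectrum_weights(),
                        depth_mean = 60,
                        offtarget_fraction = 0.02,
                        n_offtarget_sites = 1500,
                        offtarget_masked_fraction = 0.05,
                        mask_fraction = 0.45,
                        n_parental_snvs = 300,
                        n_parental_indels = 30,
                        mosaic_fraction = 0.10,
                        complex_rate_be4 = 0.8,
                        distractors = TRUE,
                        dispersion = 1) {
  spec <- list(seed = as.integer(seed), genome = genome, n_dams = n_dams,
               group_sizes = group_sizes, snv_rate = snv_rate,
               indel_rate = indel_rate, spectrum_weights = spectrum_weights,
               depth_mean = depth_mean,
               offtarget_fraction = offtarget_fraction,
               n_offtarget_sites = n_offtarget_sites,
               offtarget_masked_fraction = offtarget_masked_fraction,
               mask_fraction = mask_fraction,
               n_parental_snvs = n_parental_snvs,
               n_parental_indels = n_parental_indels,
               mosaic_fraction = mosaic_fraction,
               complex_rate_be4 = complex_rate_be4,
               distractors = isTRUE(distractors),
               dispersion = dispersion)
  groups <- c("control", "ABE", "BE4")
  if (is.null(names(genome)) || any(genome < 1e5)) {
    stop("genome must be a named vector of chromosome lengths >= 1e5")
  }
  if (!all(groups %in% names(spec$group_sizes)) ||
      !all(groups %in% names(spec$snv_rate)) ||
      !all(groups %in% names(spec$indel_rate))) {
    stop("group_sizes, snv_rate and indel_rate need names control, ABE, BE4")
  }
  if (any(spec$group_sizes < 1)) stop("group sizes must be >= 1")
  if (any(spec$snv_rate < 0) || any(spec$indel_rate < 0)) {
    stop("rates must be >= 0")
  }
  if (spec$offtarget_fraction < 0 || spec$offtarget_fraction > 1) {
    stop("offtarget_fraction must be in [0, 1]")
  }
  if (!identical(dim(spec$spectrum_weights), c(3L, 12L)) ||
      any(abs(rowSums(spec$spectrum_weights) - 1) > 1e-8)) {
    stop("spectrum_weights must be a 3 x 12 matrix with rows summing to 1")
  }
  if (spec$mask_fraction < 0 || spec$mask_fraction >= 1) {
    stop("mask_fraction must be in [0, 1)")
  }
  if (spec$dispersion < 1) stop("dispersion must be >= 1")
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic trio cohort spec (seed", x$seed, ")\n")
  cat(sprintf("  genome: %d chromosomes, %.1f Mb; mask fraction %.2f\n",
              length(x$genome), sum(x$genome) / 1e6, x$mask_fraction))
  cat(sprintf("  parents: 1 sire + %d dams; offspring: %s\n", x$n_dams,
              paste(names(x$group_sizes), x$group_sizes, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  de novo SNV rates: %s; depth %gX; off-target fraction %g\n",
              paste(names(x$snv_rate), x$snv_rate, sep = "=",
                    collapse = ", "), x$depth_mean, x$offtarget_fraction))
  invisible(x)
}

# --- internal generation helpers ------------------------------------------

draw_count <- function(n, rate, dispersion) {
  if (rate == 0) return(rep(0L, n))
  if (dispersion <= 1) return(stats::rpois(n, rate))
  size <- rate / (dispersion - 1)
  stats::rnbinom(n, mu = rate, size = size)
}

# random mask covering ~fraction of the genome, built from exponential
# interval lengths (mean ~800 bp)
sim_mask <- function(genome, fraction) {
  if (fraction <= 0) return(GenomicRanges::GRanges())
  grs <- lapply(names(genome), function(ch) {
    L <- genome[[ch]]
    target <- fraction * L
    gr <- GenomicRanges::GRanges()
    repeat {
      covered <- sum(IRanges::width(gr))
      if (covered >= target) break
      k <- max(10L, ceiling((target - covered) / 800))
      start <- floor(stats::runif(k, 1, L - 3000))
      w <- pmax(100L, ceiling(stats::rexp(k, 1 / 700)))
      gr <- GenomicRanges::reduce(gr_c(
        gr, GenomicRanges::GRanges(ch, IRanges::IRanges(start, width = w))))
    }
    gr
  })
  GenomicRanges::sort(GenomicRanges::reduce(do.call(gr_c, grs)))
}

# draw n positions whose padded window [pos-pad, pos+span-1+pad] avoids
# `avoid` and each other; returns data.frame(chrom, pos) (pos 1-based)
draw_clear_positions <- function(n, genome, avoid, span = 1, pad = 20) {
  if (n == 0) return(data.frame(chrom = character(0), pos = integer(0)))
  out_chrom <- character(0)
  out_pos <- integer(0)
  taken <- avoid
  for (iter in 1:60) {
    need <- n - length(out_pos)
    if (need <= 0) break
    m <- max(500L, 3L * need)
    chrom <- sample(names(genome), m, replace = TRUE, prob = genome)
    pos <- floor(stats::runif(m, pad + 2, genome[chrom] - span - pad - 1))
    g <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(pos - pad,
                                                 pos + span - 1 + pad))
    ok <- !overlap_any(g, taken)
    # drop candidates colliding with each other within this batch
    self <- GenomicRanges::countOverlaps(g, g) == 1
    keep <- which(ok & self)
    if (length(keep) > need) keep <- keep[seq_len(need)]
    if (length(keep)) {
      out_chrom <- c(out_chrom, chrom[keep])
      out_pos <- c(out_pos, as.integer(pos[keep]))
      taken <- gr_c(taken, g[keep])
    }
  }
  if (length(out_pos) < n) {
    stop("generation error: genome too small to place ", n,
         " variants without violating spacing constraints")
  }
  data.frame(chrom = out_chrom, pos = out_pos, stringsAsFactors = FALSE)
}

# draw n positions inside the mask, avoiding occupied windows
draw_masked_positions <- function(n, mask, occupied) {
  if (n == 0) return(data.frame(chrom = character(0), pos = integer(0)))
  w <- IRanges::width(mask)
  out_chrom <- character(0)
  out_pos <- integer(0)
  taken <- occupied
  for (iter in 1:60) {
    need <- n - length(out_pos)
    if (need <= 0) break
    m <- max(50L, 3L * need)
    iv <- sample(length(mask), m, replace = TRUE, prob = w)
    pos <- GenomicRanges::start(mask)[iv] +
      floor(stats::runif(m) * (w[iv] - 1))
    chrom <- as.character(GenomicRanges::seqnames(mask))[iv]
    g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos - 8, pos + 8))
    ok <- !overlap_any(g, taken)
    self <- GenomicRanges::countOverlaps(g, g) == 1
    keep <- which(ok & self)
    if (length(keep) > need) keep <- keep[seq_len(need)]
    if (length(keep)) {
      out_chrom <- c(out_chrom, chrom[keep])
      out_pos <- c(out_pos, as.integer(pos[keep]))
      taken <- gr_c(taken, g[keep])
    }
  }
  if (length(out_pos) < n) {
    stop("generation error: could not place ", n, " masked positions")
  }
  data.frame(chrom = out_chrom, pos = out_pos, stringsAsFactors = FALSE)
}

# depth for a passing call: Poisson(depth_mean) truncated to
# [dp_min, floor(d + 3 sqrt(d))]
rdepth_pass <- function(n, depth_mean, dp_min = 10) {
  hi <- floor(excessive_depth_cutoff(depth_mean))
  dp <- stats::rpois(n, depth_mean)
  for (i in 1:50) {
    bad <- which(dp < dp_min | dp > hi)
    if (!length(bad)) break
    dp[bad] <- stats::rpois(length(bad), depth_mean)
  }
  dp[dp < dp_min] <- dp_min
  dp[dp > hi] <- hi
  as.integer(dp)
}

# allele-supporting reads for a passing het call at allele fraction p,
# redrawn until af >= af_min and ad_alt >= 1
rad_pass <- function(dp, p, af_min = 0.10) {
  n <- length(dp)
  ad <- stats::rbinom(n, dp, p)
  for (i in 1:80) {
    bad <- which(ad < 1 | ad / dp < af_min | ad > dp - 1)
    if (!length(bad)) break
    ad[bad] <- stats::rbinom(length(bad), dp[bad], p[bad])
  }
  lo <- ceiling(pmax(1, af_min * dp))
  ad <- pmin(pmax(ad, lo), dp - 1)
  as.integer(ad)
}

# site annotations that comfortably pass the hard filters; rank-sum
# annotations are occasionally absent, as the caller omits them
rann_pass <- function(n, p_missing_ranksum = 0.1) {
  mqr <- stats::runif(n, -3, 3)
  rpr <- stats::runif(n, -3, 3)
  miss <- stats::runif(n) < p_missing_ranksum
  mqr[miss] <- NA_real_
  rpr[miss] <- NA_real_
  data.frame(QD = stats::runif(n, 10, 35), FS = stats::runif(n, 0, 20),
             MQ = stats::runif(n, 50, 60), MQRankSum = mqr,
             ReadPosRankSum = rpr, SOR = stats::runif(n, 0.3, 2.5))
}

ref_alt_for_class <- function(class_idx) {
  ra <- strsplit(SUB_CLASSES[class_idx], ">")
  data.frame(ref = vapply(ra, `[`, character(1), 1),
             alt = vapply(ra, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

rand_seq <- function(len) {
  vapply(len, function(l)
    paste(sample(BASES, l, replace = TRUE), collapse = ""), character(1))
}

# random indel ref/alt strings (anchor-base convention)
rand_indels <- function(n, max_len = 8) {
  if (n == 0) {
    return(data.frame(ref = character(0), alt = character(0)))
  }
  is_del <- stats::runif(n) < 0.5
  len <- 1L + floor(stats::runif(n) * max_len)
  anchor <- sample(BASES, n, replace = TRUE)
  tail_seq <- rand_seq(len)
  ref <- ifelse(is_del, paste0(anchor, tail_seq), anchor)
  alt <- ifelse(is_del, anchor, paste0(anchor, tail_seq))
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}
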