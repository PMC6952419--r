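# simulate_cohort(): orchestrates the generation of a full synthetic
# input bundle (see simulate.R for the primitives and cohort_spec()).
# Positions are drawn in three large batches (general pool, complex-indel
# pool, masked pool) with mutual spacing, then consumed sequentially.

write_bed <- function(gr, path) {
  if (length(gr) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

write_sv_vcf <- function(records, gt, dp, samples, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           paste0("##INFO=<ID=SU,Number=1,Type=Integer,Description=",
                  "\"Number of pieces of evidence supporting the variant ",
                  "across all samples\">"),
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  n <- nrow(records)
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  info <- sprintf("SVTYPE=%s;END=%d;SU=%d", records$svtype,
                  records$end, records$su)
  calls <- vapply(seq_along(samples), function(j) {
    paste0(ifelse(is.na(gt[, j]), "./.", gt[, j]), ":",
           na_dot(dp[, j]))
  }, character(n))
  if (n == 1) calls <- matrix(calls, nrow = 1)
  body <- paste(records$chrom, records$start + 1L, ".", "N",
                paste0("<", records$svtype, ">"),
                format_num(records$qual), ".", info, "GT:DP", sep = "\t")
  if (length(samples) > 0) {
    body <- paste(body, apply(calls, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a truth table
#'
#' @param truth data.frame with columns `sample`, `chrom`, `pos`, `end`,
#'   `ref`, `alt`, `vtype`, `category`.
#' @param path output path (tab-separated with header).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  cols <- c("sample", "chrom", "pos", "end", "ref", "alt", "vtype",
            "category")
  df <- as.data.frame(truth)[, cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#' @param path path to the truth file.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(sample = "character",
                                   chrom = "character", pos = "integer",
                                   end = "integer", ref = "character",
                                   alt = "character", vtype = "character",
                                   category = "character"))
}

#' Generate a synthetic trio cohort bundle
#'
#' Writes a complete, self-consistent input bundle for the pipeline --
#' `cohort.vcf` (multi-sample small variants), `complex.vcf` (SV dialect
#' with SVTYPE/END/SU), `mask_repeats.bed` + `mask_blacklist.bed`,
#' `offtargets.tsv`, `pedigree.tsv`, `truth.tsv` and a `params.yaml`
#' echo -- deterministic given the spec and its seed.
#'
#' Parents carry heterozygous germline variants that each offspring
#' inherits with probability 1/2; per-offspring de novo variants are drawn
#' at the group rates with group-specific spectra, given depths, allele
#' fractions and site annotations that satisfy every filter; a fraction
#' `offtarget_fraction` of de novo SNVs is placed inside retained
#' predicted off-target sites; and (optionally) one distractor per filter
#' category per offspring is planted that violates exactly its intended
#' filter.  The truth table records every planted variant and its
#' category.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return an object of class `"cohort_bundle"`: list with `dir`, named
#'   file `paths`, the `truth` data.frame, the `pedigree` data.frame and
#'   the `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = tempfile("cohort")) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  genome <- spec$genome
  d <- spec$depth_mean
  cutoff <- excessive_depth_cutoff(d)
  af_min <- 0.10
  dp_min <- 10

  ## ---- mask ----
  mask <- sim_mask(genome, spec$mask_fraction)
  is_rep <- stats::runif(length(mask)) < 0.5
  write_bed(mask[is_rep], file.path(dir, "mask_repeats.bed"))
  write_bed(mask[!is_rep], file.path(dir, "mask_blacklist.bed"))

  ## ---- predicted off-target sites ----
  n_masked_sites <- round(spec$n_offtarget_sites *
                            spec$offtarget_masked_fraction)
  n_clear_sites <- spec$n_offtarget_sites - n_masked_sites
  cs <- draw_clear_positions(n_clear_sites, genome, mask, span = 23,
                             pad = 25)
  sites_clear <- data.frame(chrom = cs$chrom, start = cs$pos - 1L,
                            end = cs$pos - 1L + 23L,
                            stringsAsFactors = FALSE)
  occ_masked <- GenomicRanges::GRanges()
  ms <- draw_masked_positions(n_masked_sites, mask, occ_masked)
  if (nrow(ms)) {
    occ_masked <- gr_c(occ_masked,
                       GenomicRanges::GRanges(
                         ms$chrom, IRanges::IRanges(ms$pos - 30,
                                                    ms$pos + 30)))
  }
  sites_all <- rbind(sites_clear,
                     data.frame(chrom = ms$chrom, start = ms$pos - 1L,
                                end = ms$pos - 1L + 23L,
                                stringsAsFactors = FALSE))
  sites_all$mismatches <- sample(1:4, nrow(sites_all), replace = TRUE)
  sites_all <- sites_all[sample(nrow(sites_all)), , drop = FALSE]
  utils::write.table(sites_all, file.path(dir, "offtargets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # positions inside off-target sites, drawn without replacement
  ot_pool <- expand.grid(site = seq_len(nrow(sites_clear)), offset = 0:22)
  ot_pool <- ot_pool[sample(nrow(ot_pool)), , drop = FALSE]
  ot_ptr <- 0L
  take_ot_positions <- function(k) {
    if (k == 0) return(data.frame(chrom = character(0), pos = integer(0)))
    if (ot_ptr + k > nrow(ot_pool)) {
      stop("generation error: off-target site pool exhausted")
    }
    sel <- ot_pool[ot_ptr + seq_len(k), , drop = FALSE]
    ot_ptr <<- ot_ptr + k
    data.frame(chrom = sites_clear$chrom[sel$site],
               pos = sites_clear$start[sel$site] + sel$offset + 1L,
               stringsAsFactors = FALSE)
  }

  ## ---- pedigree ----
  sire <- "SIRE1"
  dams <- sprintf("DAM%d", seq_len(spec$n_dams))
  parents <- c(sire, dams)
  groups <- c("control", "ABE", "BE4")
  prefix <- c(control = "CTL", ABE = "ABE", BE4 = "BE4")
  off_ids <- unlist(lapply(groups, function(g)
    sprintf("%s%02d", prefix[[g]], seq_len(spec$group_sizes[[g]]))))
  off_group <- rep(groups, spec$group_sizes[groups])
  off_dam <- dams[((seq_along(off_ids) - 1L) %% length(dams)) + 1L]
  pedigree <- pedigree_cohort(data.frame(
    sample_id = c(parents, off_ids),
    role = c(rep("parent", length(parents)),
             rep("offspring", length(off_ids))),
    group = c(rep(NA_character_, length(parents)), off_group),
    sire_id = c(rep(NA_character_, length(parents)),
                rep(sire, length(off_ids))),
    dam_id = c(rep(NA_character_, length(parents)), off_dam),
    stringsAsFactors = FALSE))
  ped_out <- as.data.frame(pedigree)
  for (k in c("group", "sire_id", "dam_id")) {
    ped_out[[k]][is.na(ped_out[[k]])] <- "."
  }
  utils::write.table(ped_out, file.path(dir, "pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  samples <- c(parents, off_ids)
  n_off <- length(off_ids)

  ## ---- per-offspring counts and flags ----
  n_snv <- integer(n_off)
  n_ind <- integer(n_off)
  k_cx <- integer(n_off)
  coin_l <- vector("list", n_off)
  for (i in seq_len(n_off)) {
    g <- off_group[i]
    n_snv[i] <- draw_count(1, spec$snv_rate[[g]], spec$dispersion)
    coin_l[[i]] <- stats::runif(n_snv[i]) < spec$offtarget_fraction
    ni <- draw_count(1, spec$indel_rate[[g]], spec$dispersion)
    if (spec$distractors && ni == 0) ni <- 1L
    n_ind[i] <- ni
    k_cx[i] <- if (g == "BE4" && spec$complex_rate_be4 > 0) {
      stats::rpois(1, spec$complex_rate_be4)
    } else 0L
  }

  ## ---- position pools ----
  # padded site footprints are excluded from the general pool so only
  # deliberately placed SNVs fall inside predicted sites
  site_windows <- GenomicRanges::GRanges(
    sites_clear$chrom, IRanges::IRanges(sites_clear$start - 25L,
                                        sites_clear$end + 25L))
  blocked <- GenomicRanges::reduce(gr_c(mask, site_windows))
  n_distract_small <- if (spec$distractors) 6L * n_off else 0L
  n_general <- length(parents) *
    (spec$n_parental_snvs + spec$n_parental_indels) +
    sum(n_snv) - sum(vapply(coin_l, sum, numeric(1))) +
    sum(n_ind) + n_distract_small
  pool_small <- draw_clear_positions(n_general, genome, blocked,
                                     span = 9L, pad = 20)
  if (n_general > 0) {
    blocked <- gr_c(blocked, GenomicRanges::GRanges(
      pool_small$chrom, IRanges::IRanges(pool_small$pos - 20L,
                                         pool_small$pos + 29L)))
  }
  n_cx_total <- sum(k_cx) + (if (spec$distractors) 2L * n_off else 0L)
  pool_cx <- draw_clear_positions(n_cx_total, genome, blocked,
                                  span = 520L, pad = 20)
  pool_masked <- draw_masked_positions(
    if (spec$distractors) n_off else 0L, mask, occ_masked)
  p_small <- 0L; p_cx <- 0L; p_masked <- 0L
  take_small <- function(k) {
    if (k == 0) return(data.frame(chrom = character(0), pos = integer(0)))
    sel <- pool_small[p_small + seq_len(k), , drop = FALSE]
    p_small <<- p_small + k
    sel
  }
  take_cx <- function() {
    p_cx <<- p_cx + 1L
    pool_cx[p_cx, , drop = FALSE]
  }
  take_masked <- function() {
    p_masked <<- p_masked + 1L
    pool_masked[p_masked, , drop = FALSE]
  }

  ## ---- accumulators ----
  vars_l <- list(); calls_l <- list(); truth_l <- list()
  n_var <- 0L
  add_variants <- function(chrom, pos, ref, alt, ann) {
    k <- length(pos)
    if (k == 0) return(integer(0))
    uid <- n_var + seq_len(k)
    n_var <<- n_var + k
    vars_l[[length(vars_l) + 1L]] <<- data.frame(
      uid = uid, chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      ann, stringsAsFactors = FALSE)
    uid
  }
  add_call <- function(uid, sample, gt, ad_ref, ad_alt, dp) {
    if (length(uid) == 0) return(invisible(NULL))
    calls_l[[length(calls_l) + 1L]] <<- data.frame(
      uid = uid, sample = sample, gt = gt,
      ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt),
      dp = as.integer(dp), stringsAsFactors = FALSE)
    invisible(NULL)
  }
  add_truth <- function(sample, chrom, pos, end, ref, alt, vtype,
                        category) {
    if (length(pos) == 0) return(invisible(NULL))
    truth_l[[length(truth_l) + 1L]] <<- data.frame(
      sample = sample, chrom = chrom, pos = as.integer(pos),
      end = as.integer(end), ref = ref, alt = alt, vtype = vtype,
      category = category, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  pass_call <- function(uid, sample, p_af = NULL) {
    k <- length(uid)
    if (k == 0) return(invisible(NULL))
    dp <- rdepth_pass(k, d, dp_min)
    if (is.null(p_af)) p_af <- rep(0.5, k)
    ad_alt <- rad_pass(dp, p_af, af_min)
    add_call(uid, sample, "0/1", dp - ad_alt, ad_alt, dp)
  }

  ## ---- parental germline variants ----
  parent_vars <- list()
  w_bg <- spec$spectrum_weights["control", ]
  for (p in parents) {
    ps <- take_small(spec$n_parental_snvs)
    cls <- sample(12, spec$n_parental_snvs, replace = TRUE, prob = w_bg)
    ra <- ref_alt_for_class(cls)
    uid_s <- add_variants(ps$chrom, ps$pos, ra$ref, ra$alt,
                          rann_pass(spec$n_parental_snvs))
    pi <- take_small(spec$n_parental_indels)
    ria <- rand_indels(spec$n_parental_indels)
    uid_i <- add_variants(pi$chrom, pi$pos, ria$ref, ria$alt,
                          rann_pass(spec$n_parental_indels))
    uid <- c(uid_s, uid_i)
    pass_call(uid, p)
    parent_vars[[p]] <- data.frame(
      uid = uid, chrom = c(ps$chrom, pi$chrom), pos = c(ps$pos, pi$pos),
      ref = c(ra$ref, ria$ref), alt = c(ra$alt, ria$alt),
      stringsAsFactors = FALSE)
  }

  ## ---- complex indel accumulators ----
  cx_l <- list()
  add_complex <- function(sample, chrom, start0, end0, qual, su,
                          category) {
    cx_l[[length(cx_l) + 1L]] <<- data.frame(
      sample = sample, chrom = chrom, start = as.integer(start0),
      end = as.integer(end0), svtype = "DEL", qual = qual,
      su = as.integer(su),
      dp = rdepth_pass(length(start0), d, dp_min),
      stringsAsFactors = FALSE)
    add_truth(sample, chrom, start0 + 1L, end0, ".", ".", "complex",
              category)
  }

  ## ---- per-offspring variants ----
  for (i in seq_len(n_off)) {
    o <- off_ids[i]
    g <- off_group[i]
    w <- spec$spectrum_weights[g, ]

    # Mendelian inheritance from sire and dam
    for (p in c(sire, off_dam[i])) {
      pv <- parent_vars[[p]]
      inh <- stats::runif(nrow(pv)) < 0.5
      if (any(inh)) {
        pass_call(pv$uid[inh], o)
        vt <- ifelse(nchar(pv$ref[inh]) == 1 & nchar(pv$alt[inh]) == 1,
                     "snv", "indel")
        add_truth(o, pv$chrom[inh], pv$pos[inh],
                  pv$pos[inh] + nchar(pv$ref[inh]) - 1L,
                  pv$ref[inh], pv$alt[inh], vt, "inherited")
      }
    }

    # de novo SNVs
    if (n_snv[i] > 0) {
      coin <- coin_l[[i]]
      cls <- sample(12, n_snv[i], replace = TRUE, prob = w)
      ra <- ref_alt_for_class(cls)
      pos_df <- data.frame(chrom = character(n_snv[i]),
                           pos = integer(n_snv[i]),
                           stringsAsFactors = FALSE)
      pos_df[!coin, ] <- take_small(sum(!coin))
      pos_df[coin, ] <- take_ot_positions(sum(coin))
      mosaic <- g != "control" & stats::runif(n_snv[i]) < spec$mosaic_fraction
      p_af <- ifelse(mosaic, stats::runif(n_snv[i], 0.2, 0.3), 0.5)
      uid <- add_variants(pos_df$chrom, pos_df$pos, ra$ref, ra$alt,
                          rann_pass(n_snv[i]))
      pass_call(uid, o, p_af)
      add_truth(o, pos_df$chrom, pos_df$pos, pos_df$pos, ra$ref, ra$alt,
                "snv", ifelse(coin, "offtarget_coincident", "denovo_pass"))
      # occasionally a parent is uncalled at a de novo site; the variant
      # still passes (subtraction only removes alleles present in parents)
      unc <- which(stats::runif(n_snv[i]) < 0.005)
      if (length(unc)) {
        add_call(uid[unc], sample(c(sire, off_dam[i]), 1),
                 NA_character_, NA, NA, NA)
      }
    }

    # de novo simple indels
    anchor <- NULL
    if (n_ind[i] > 0) {
      pi <- take_small(n_ind[i])
      ria <- rand_indels(n_ind[i])
      uid <- add_variants(pi$chrom, pi$pos, ria$ref, ria$alt,
                          rann_pass(n_ind[i]))
      pass_call(uid, o)
      add_truth(o, pi$chrom, pi$pos, pi$pos + nchar(ria$ref) - 1L,
                ria$ref, ria$alt, "indel", "denovo_pass")
      anchor <- list(chrom = pi$chrom[1], pos = pi$pos[1],
                     ref = ria$ref[1], alt = ria$alt[1])
    }

    # complex deletions (BE4-specific proximal-deletion phenotype)
    for (jj in seq_len(k_cx[i])) {
      len <- 50L + floor(stats::runif(1) * 450)
      cp <- take_cx()
      add_complex(o, cp$chrom, cp$pos - 1L, cp$pos - 1L + len,
                  stats::runif(1, 150, 900), 5L + stats::rpois(1, 10),
                  "denovo_pass")
    }

    # distractors: one per filter category, each violating exactly its
    # intended predicate
    if (spec$distractors) {
      bg_class <- function() {
        ref_alt_for_class(sample(12, 1, prob = w_bg))
      }
      # site_hard_snv: QD below threshold
      pd <- take_small(1); ra1 <- bg_class()
      ann <- rann_pass(1, p_missing_ranksum = 0); ann$QD <- 0.5
      uid <- add_variants(pd$chrom, pd$pos, ra1$ref, ra1$alt, ann)
      pass_call(uid, o)
      add_truth(o, pd$chrom, pd$pos, pd$pos, ra1$ref, ra1$alt, "snv",
                "distractor:site_hard_snv")
      # site_hard_indel: FS above the indel threshold
      pd <- take_small(1); ri1 <- rand_indels(1)
      ann <- rann_pass(1, p_missing_ranksum = 0); ann$FS <- 250
      uid <- add_variants(pd$chrom, pd$pos, ri1$ref, ri1$alt, ann)
      pass_call(uid, o)
      add_truth(o, pd$chrom, pd$pos, pd$pos + nchar(ri1$ref) - 1L,
                ri1$ref, ri1$alt, "indel", "distractor:site_hard_indel")
      # mask: otherwise-perfect SNV inside the mask
      pm <- take_masked(); ra1 <- bg_class()
      uid <- add_variants(pm$chrom, pm$pos, ra1$ref, ra1$alt, rann_pass(1))
      pass_call(uid, o)
      add_truth(o, pm$chrom, pm$pos, pm$pos, ra1$ref, ra1$alt, "snv",
                "distractor:mask")
      # genotype: homozygous-reference call with alt reads
      pd <- take_small(1); ra1 <- bg_class()
      uid <- add_variants(pd$chrom, pd$pos, ra1$ref, ra1$alt, rann_pass(1))
      add_call(uid, o, "0/0", 40L, 20L, 60L)
      add_truth(o, pd$chrom, pd$pos, pd$pos, ra1$ref, ra1$alt, "snv",
                "distractor:genotype")
      # min_depth: depth below dp_min
      pd <- take_small(1); ra1 <- bg_class()
      uid <- add_variants(pd$chrom, pd$pos, ra1$ref, ra1$alt, rann_pass(1))
      add_call(uid, o, "0/1", 3L, 3L, 6L)
      add_truth(o, pd$chrom, pd$pos, pd$pos, ra1$ref, ra1$alt, "snv",
                "distractor:min_depth")
      # excess_depth: depth above d + 3 sqrt(d)
      pd <- take_small(1); ra1 <- bg_class()
      dp_x <- as.integer(ceiling(cutoff) + 40)
      uid <- add_variants(pd$chrom, pd$pos, ra1$ref, ra1$alt, rann_pass(1))
      add_call(uid, o, "0/1", dp_x - dp_x %/% 2L, dp_x %/% 2L, dp_x)
      add_truth(o, pd$chrom, pd$pos, pd$pos, ra1$ref, ra1$alt, "snv",
                "distractor:excess_depth")
      # allele_fraction: af below af_min
      pd <- take_small(1); ra1 <- bg_class()
      uid <- add_variants(pd$chrom, pd$pos, ra1$ref, ra1$alt, rann_pass(1))
      add_call(uid, o, "0/1", 57L, 3L, 60L)
      add_truth(o, pd$chrom, pd$pos, pd$pos, ra1$ref, ra1$alt, "snv",
                "distractor:allele_fraction")
      # near_indel: SNV within the window of this sample's first passing
      # de novo indel
      b2 <- if (nchar(anchor$ref) > nchar(anchor$alt)) {
        anchor$pos + nchar(anchor$ref) - 1L
      } else anchor$pos + 1L
      np <- b2 + sample(1:5, 1)
      ra1 <- bg_class()
      uid <- add_variants(anchor$chrom, np, ra1$ref, ra1$alt, rann_pass(1))
      pass_call(uid, o)
      add_truth(o, anchor$chrom, np, np, ra1$ref, ra1$alt, "snv",
                "distractor:near_indel")
      # sv_overlap: simple deletion inside a passing complex deletion
      cp <- take_cx()
      start0 <- cp$pos - 1L
      add_complex(o, cp$chrom, start0, start0 + 300L,
                  stats::runif(1, 300, 900), 12L, "denovo_pass")
      sp <- cp$pos + 100L
      ref_del <- paste0(sample(BASES, 1), rand_seq(3))
      alt_del <- substr(ref_del, 1, 1)
      uid <- add_variants(cp$chrom, sp, ref_del, alt_del, rann_pass(1))
      pass_call(uid, o)
      add_truth(o, cp$chrom, sp, sp + nchar(ref_del) - 1L, ref_del,
                alt_del, "indel", "distractor:sv_overlap")
      # complex_su: complex deletion with insufficient supporting evidence
      cp <- take_cx()
      cx_l[[length(cx_l) + 1L]] <- data.frame(
        sample = o, chrom = cp$chrom, start = cp$pos - 1L,
        end = cp$pos - 1L + 120L, svtype = "DEL",
        qual = stats::runif(1, 300, 900), su = 2L,
        dp = rdepth_pass(1, d, dp_min), stringsAsFactors = FALSE)
      add_truth(o, cp$chrom, cp$pos, cp$pos - 1L + 120L, ".", ".",
                "complex", "distractor:complex_su")
    }
  }

  ## ---- assemble and write the small-variant VCF ----
  vars <- do.call(rbind, vars_l)
  calls <- do.call(rbind, calls_l)
  truth <- if (length(truth_l)) do.call(rbind, truth_l) else
    data.frame(sample = character(0), chrom = character(0),
               pos = integer(0), end = integer(0), ref = character(0),
               alt = character(0), vtype = character(0),
               category = character(0))
  ns <- length(samples)
  if (is.null(vars)) {
    vars <- data.frame(uid = integer(0), chrom = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0))
  }
  ord <- order(factor(vars$chrom, levels = names(genome)), vars$pos)
  vars <- vars[ord, , drop = FALSE]
  rowmap <- integer(n_var)
  rowmap[vars$uid] <- seq_len(n_var)
  gt_m <- matrix("0/0", n_var, ns)
  dp_m <- matrix(stats::rpois(n_var * ns, d), n_var, ns)
  adr_m <- dp_m
  ada_m <- matrix(0L, n_var, ns)
  if (!is.null(calls) && nrow(calls)) {
    idx <- cbind(rowmap[calls$uid], match(calls$sample, samples))
    gt_m[idx] <- calls$gt
    adr_m[idx] <- calls$ad_ref
    ada_m[idx] <- calls$ad_alt
    dp_m[idx] <- calls$dp
  }
  ann_cols <- intersect(ANNOTATION_KEYS, names(vars))
  vs <- variant_set(vars[, c("chrom", "pos", "ref", "alt", ann_cols)],
                    gt_m, adr_m, ada_m, dp_m, samples)
  write_variant_vcf(vs, file.path(dir, "cohort.vcf"), contigs = genome)

  ## ---- assemble and write the complex-indel VCF ----
  cx <- if (length(cx_l)) do.call(rbind, cx_l) else
    data.frame(sample = character(0), chrom = character(0),
               start = integer(0), end = integer(0), svtype = character(0),
               qual = numeric(0), su = integer(0), dp = integer(0))
  cx <- cx[order(factor(cx$chrom, levels = names(genome)), cx$start), ,
           drop = FALSE]
  ncx <- nrow(cx)
  cgt <- matrix("0/0", ncx, ns)
  cdp <- matrix(stats::rpois(ncx * ns, d), ncx, ns)
  if (ncx) {
    idx <- cbind(seq_len(ncx), match(cx$sample, samples))
    cgt[idx] <- "0/1"
    cdp[idx] <- cx$dp
  }
  write_sv_vcf(cx[, c("chrom", "start", "end", "svtype", "qual", "su")],
               cgt, cdp, samples, file.path(dir, "complex.vcf"),
               contigs = genome)

  write_truth(truth, file.path(dir, "truth.tsv"))
  spec_echo <- unclass(spec)
  spec_echo$genome <- as.list(spec$genome)
  spec_echo$group_sizes <- as.list(spec$group_sizes)
  spec_echo$snv_rate <- as.list(spec$snv_rate)
  spec_echo$indel_rate <- as.list(spec$indel_rate)
  spec_echo$spectrum_weights <- apply(spec$spectrum_weights, 1, as.list,
                                      simplify = FALSE)
  yaml::write_yaml(spec_echo, file.path(dir, "params.yaml"))

  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             sv_vcf = file.path(dir, "complex.vcf"),
             mask_repeats = file.path(dir, "mask_repeats.bed"),
             mask_blacklist = file.path(dir, "mask_blacklist.bed"),
             offtargets = file.path(dir, "offtargets.tsv"),
             pedigree = file.path(dir, "pedigree.tsv"),
             truth = file.path(dir, "truth.tsv"),
             params = file.path(dir, "params.yaml"))
  structure(list(dir = dir, paths = paths, truth = truth,
                 pedigree = pedigree, spec = spec),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic cohort bundle in", x$dir, "\n")
  cat("  samples:", nrow(x$pedigree), " planted variants:",
      nrow(x$truth), "\n")
  tab <- table(x$truth$category)
  cat("  truth categories:\n")
  for (nm in names(tab)) cat(sprintf("    %-28s %d\n", nm, tab[[nm]]))
  invisible(x)
}
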