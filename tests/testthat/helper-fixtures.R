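# Test helpers: in-code fixtures and independent brute-force oracles.

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##contig=<ID=chr2,length=1000000>",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"x\">",
            c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_fixture_vcf <- function(body, samples = c("S1", "S2"),
                              path = tempfile(fileext = ".vcf")) {
  writeLines(c(vcf_header(samples), body), path)
  path
}

write_fixture_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

mask_from_df <- function(df) {
  if (nrow(df) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end)))
}

# per-base membership oracle: is any reference-spanned base of the variant
# inside a half-open 0-based mask interval?
oracle_overlaps <- function(chrom, pos, ref, mask_df) {
  if (nrow(mask_df) == 0) return(FALSE)
  for (b in pos:(pos + nchar(ref) - 1L)) {
    z <- b - 1L
    if (any(mask_df$chrom == chrom & mask_df$start <= z & z < mask_df$end)) {
      return(TRUE)
    }
  }
  FALSE
}

# random small trio cohort built directly in memory (two parents, two
# offspring), with annotations, depths and genotypes straddling every
# threshold of the cascade
rand_mini_cohort <- function(seed) {
  set.seed(seed)
  samples <- c("SIRE", "DAM", "K1", "K2")
  ped <- pedigree_cohort(data.frame(
    sample_id = samples,
    role = c("parent", "parent", "offspring", "offspring"),
    group = c(NA, NA, "control", "BE4"),
    sire_id = c(NA, NA, "SIRE", "SIRE"),
    dam_id = c(NA, NA, "DAM", "DAM"),
    stringsAsFactors = FALSE))
  n <- sample(8:18, 1)
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  pos <- sample(2000, n)
  is_snv <- stats::runif(n) < 0.6
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    if (is_snv[i]) {
      ra <- sample(c("A", "C", "G", "T"), 2)
      ref[i] <- ra[1]; alt[i] <- ra[2]
    } else if (stats::runif(1) < 0.5) {
      ref[i] <- paste(sample(c("A", "C", "G", "T"),
                             1 + sample(1:6, 1), replace = TRUE),
                      collapse = "")
      alt[i] <- substr(ref[i], 1, 1)
    } else {
      alt[i] <- paste(sample(c("A", "C", "G", "T"),
                             1 + sample(1:6, 1), replace = TRUE),
                      collapse = "")
      ref[i] <- substr(alt[i], 1, 1)
    }
  }
  maybe_na <- function(x, p = 0.3) ifelse(stats::runif(length(x)) < p,
                                          NA_real_, x)
  variants <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    QD = maybe_na(stats::runif(n, 0, 6)),
    FS = maybe_na(stats::runif(n, 0, 300)),
    MQ = maybe_na(stats::runif(n, 20, 60)),
    MQRankSum = maybe_na(stats::runif(n, -20, 5)),
    ReadPosRankSum = maybe_na(stats::runif(n, -25, 5)),
    SOR = maybe_na(stats::runif(n, 0, 12)),
    stringsAsFactors = FALSE)
  ns <- length(samples)
  gt <- matrix(sample(c("0/0", "0/1", "1/1", NA), n * ns, replace = TRUE,
                      prob = c(0.35, 0.35, 0.2, 0.1)), n, ns)
  dp <- matrix(sample(0:130, n * ns, replace = TRUE), n, ns)
  ad_alt <- matrix(stats::rbinom(n * ns, as.vector(dp), 0.35), n, ns)
  ad_ref <- dp - ad_alt
  miss_ad <- matrix(stats::runif(n * ns) < 0.1, n, ns)
  ad_ref[miss_ad] <- NA_integer_
  ad_alt[miss_ad] <- NA_integer_
  vs <- variant_set(variants, gt, ad_ref, ad_alt, dp, samples)
  k <- sample(2:5, 1)
  mask_df <- data.frame(chrom = sample(c("chr1", "chr2"), k, replace = TRUE),
                        start = sample(0:1900, k),
                        stringsAsFactors = FALSE)
  mask_df$end <- mask_df$start + sample(5:80, k, replace = TRUE)
  m <- sample(1:3, 1)
  sv_rec <- data.frame(chrom = sample(c("chr1", "chr2"), m, replace = TRUE),
                       start = sample(0:1900, m),
                       stringsAsFactors = FALSE)
  sv_rec$end <- sv_rec$start + sample(20:200, m, replace = TRUE)
  sv_rec$svtype <- "DEL"
  sv_rec$qual <- stats::runif(m, 0, 500)
  sv_rec$su <- sample(0:20, m, replace = TRUE)
  sv <- structure(list(
    records = sv_rec,
    gt = matrix(sample(c("0/0", "0/1", "1/1", NA), m * ns, replace = TRUE),
                m, ns, dimnames = list(NULL, samples)),
    dp = matrix(sample(c(NA, 5:130), m * ns, replace = TRUE), m, ns,
                dimnames = list(NULL, samples)),
    samples = samples), class = "sv_set")
  list(vs = vs, sv = sv, mask_df = mask_df, mask = mask_from_df(mask_df),
       ped = ped)
}

# Joint single-pass oracle for the whole cascade: evaluates every predicate
# with scalar loops, independent of the staged implementation.
oracle_denovo <- function(vs, sv, mask_df, ped, cfg = filter_config()) {
  va <- vs$variants
  n <- nrow(va)
  cutoff <- cfg$d + 3 * sqrt(cfg$d)
  hard_ok <- function(i) {
    a <- va[i, ]
    if (a$vclass == "SNV") {
      h <- cfg$snv_hard
      !((!is.na(a$QD) && a$QD < h$QD_min) ||
          (!is.na(a$FS) && a$FS > h$FS_max) ||
          (!is.na(a$MQ) && a$MQ < h$MQ_min) ||
          (!is.na(a$MQRankSum) && a$MQRankSum < h$MQRankSum_min) ||
          (!is.na(a$ReadPosRankSum) &&
             a$ReadPosRankSum < h$ReadPosRankSum_min) ||
          (!is.na(a$SOR) && a$SOR > h$SOR_max))
    } else {
      h <- cfg$indel_hard
      !((!is.na(a$QD) && a$QD < h$QD_min) ||
          (!is.na(a$FS) && a$FS > h$FS_max) ||
          (!is.na(a$ReadPosRankSum) &&
             a$ReadPosRankSum < h$ReadPosRankSum_min) ||
          (!is.na(a$SOR) && a$SOR > h$SOR_max))
    }
  }
  off <- ped[ped$role == "offspring", , drop = FALSE]
  out <- list()
  cx_out <- list()
  for (r in seq_len(nrow(off))) {
    o <- off$sample_id[r]
    parents <- stats::na.omit(c(off$sire_id[r], off$dam_id[r]))
    stage1 <- logical(n)
    for (i in seq_len(n)) {
      gt <- vs$gt[i, o]
      dp <- vs$dp[i, o]
      adr <- vs$ad_ref[i, o]; ada <- vs$ad_alt[i, o]
      ok <- hard_ok(i) &&
        !oracle_overlaps(va$chrom[i], va$pos[i], va$ref[i], mask_df) &&
        !is.na(gt) && gt %in% c("0/1", "1/1") &&
        !is.na(dp) && dp >= cfg$dp_min && dp <= cutoff
      if (ok && va$vclass[i] == "SNV") {
        denom <- adr + ada
        ok <- !is.na(denom) && denom > 0 && ada / denom >= cfg$af_min
      }
      stage1[i] <- ok
    }
    indels1 <- which(stage1 & va$vclass != "SNV")
    alive <- stage1
    # SNVs near surviving indel borders
    for (i in which(stage1 & va$vclass == "SNV")) {
      for (j in indels1) {
        if (va$chrom[j] != va$chrom[i]) next
        if (nchar(va$ref[j]) > nchar(va$alt[j])) {
          borders <- c(va$pos[j], va$pos[j] + nchar(va$ref[j]) - 1L)
        } else {
          borders <- c(va$pos[j], va$pos[j] + 1L)
        }
        if (min(abs(va$pos[i] - borders)) <= cfg$indel_window) {
          alive[i] <- FALSE
        }
      }
    }
    # simple indels overlapping carried complex intervals
    if (!is.null(sv)) {
      for (i in indels1) {
        span <- c(va$pos[i], va$pos[i] + nchar(va$ref[i]) - 1L)
        for (j in seq_len(nrow(sv$records))) {
          g <- sv$gt[j, o]
          if (is.na(g) || !grepl("1", g)) next
          if (sv$records$chrom[j] != va$chrom[i]) next
          lo <- sv$records$start[j] + 1L
          hi <- sv$records$end[j]
          if (span[2] >= lo && span[1] <= hi) alive[i] <- FALSE
        }
      }
    }
    # parental subtraction
    for (i in which(alive)) {
      for (p in parents) {
        g <- vs$gt[i, p]
        if (!is.na(g) && grepl("1", g)) alive[i] <- FALSE
      }
    }
    out[[o]] <- data.frame(sample = rep(o, sum(alive)),
                           va[alive, c("chrom", "pos", "ref", "alt"),
                              drop = FALSE],
                           row.names = NULL)
    # complex indels
    if (!is.null(sv)) {
      keep <- logical(nrow(sv$records))
      for (j in seq_len(nrow(sv$records))) {
        g <- sv$gt[j, o]
        dpj <- sv$dp[j, o]
        rec <- sv$records[j, ]
        masked <- FALSE
        if (nrow(mask_df)) {
          masked <- any(mask_df$chrom == rec$chrom &
                          mask_df$start < rec$end & rec$start < mask_df$end)
        }
        keep[j] <- !is.na(g) && g %in% c("0/1", "1/1") &&
          !is.na(rec$qual) && rec$qual >= cfg$sv_qual_min &&
          !is.na(dpj) && dpj <= cutoff &&
          !is.na(rec$su) && rec$su >= cfg$sv_su_min && !masked
      }
      cx_out[[o]] <- data.frame(sample = rep(o, sum(keep)),
                                sv$records[keep, c("chrom", "start", "end"),
                                           drop = FALSE],
                                row.names = NULL)
    }
  }
  list(small = do.call(rbind, out),
       complex = if (length(cx_out)) do.call(rbind, cx_out) else NULL)
}

small_key <- function(df) paste(df$sample, df$chrom, df$pos, df$ref, df$alt)

# compact synthetic spec for fast tests
small_cohort_spec <- function(seed, ...) {
  defaults <- list(
    seed = seed,
    genome = c(chr1 = 2e6, chr2 = 2e6),
    n_dams = 2,
    group_sizes = c(control = 2, ABE = 2, BE4 = 2),
    snv_rate = c(control = 12, ABE = 10, BE4 = 25),
    indel_rate = c(control = 4, ABE = 4, BE4 = 4),
    n_offtarget_sites = 120,
    n_parental_snvs = 40,
    n_parental_indels = 6,
    mask_fraction = 0.3)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_spec, args)
}

run_bundle <- function(b, config = filter_config(), out_dir = NULL) {
  run_denovo_pipeline(
    vcf = b$paths[["vcf"]], pedigree = b$paths[["pedigree"]],
    mask_beds = c(b$paths[["mask_repeats"]], b$paths[["mask_blacklist"]]),
    sv_vcf = b$paths[["sv_vcf"]], offtargets = b$paths[["offtargets"]],
    config = config, out_dir = out_dir)
}

subset_variant_set_for_test <- function(vs, idx) {
  variant_set(vs$variants[idx, , drop = FALSE],
              vs$gt[idx, , drop = FALSE],
              vs$ad_ref[idx, , drop = FALSE],
              vs$ad_alt[idx, , drop = FALSE],
              vs$dp[idx, , drop = FALSE], vs$samples)
}

truth_small_pass <- function(truth) {
  truth[truth$category %in% c("denovo_pass", "offtarget_coincident") &
          truth$vtype != "complex", , drop = FALSE]
}
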