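#' @noRd
BASES <- c("A", "C", "G", "T")

#' Classify a variant by its REF/ALT alleles
#'
#' @param ref,alt character vectors of REF and ALT allele strings
#'   (bi-allelic; multi-allelic records must be split first).
#' @return character vector with values `"SNV"`, `"insertion"` or
#'   `"deletion"`.
#' @examples
#' variant_class(c("A", "A", "ACG"), c("T", "ATT", "A"))
#' @export
variant_class <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  out <- character(length(ref))
  out[nr == 1L & na == 1L] <- "SNV"
  out[na > nr] <- "insertion"
  out[na < nr] <- "deletion"
  if (any(out == "")) {
    stop("cannot classify variant with len(ref) == len(alt) > 1; ",
         "records must be normalized to SNV/insertion/deletion")
  }
  out
}

# canonical chromosome naming: "chr"-prefixed (UCSC/mm10 convention)
normalize_chrom <- function(chrom) {
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

ANNOTATION_KEYS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")

#' Construct a multi-sample small-variant set
#'
#' The in-memory container for normalized bi-allelic small variants with
#' per-sample genotype calls.  Usually produced by [read_multisample_vcf()];
#' the constructor is exported so synthetic sets can be built directly.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based position
#'   of the first REF base), `ref`, `alt`, and optionally the site
#'   annotations `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `SOR`
#'   (`NA` where the caller did not emit them).
#' @param gt character matrix (variants x samples) of genotypes
#'   (`"0/0"`, `"0/1"`, `"1/1"`, `NA` for missing).
#' @param ad_ref,ad_alt,dp integer matrices (variants x samples) of
#'   REF-supporting reads, ALT-supporting reads and total depth (`NA`
#'   allowed).
#' @param samples character vector of sample names, in VCF column order.
#' @return an object of class `"variant_set"`.
#' @export
variant_set <- function(variants, gt, ad_ref, ad_alt, dp, samples) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  n <- nrow(variants)
  for (m in list(gt, ad_ref, ad_alt, dp)) {
    stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == length(samples))
  }
  variants$chrom <- normalize_chrom(as.character(variants$chrom))
  variants$pos <- as.integer(variants$pos)
  if (n > 0 && any(variants$pos < 1L)) stop("variant pos must be >= 1")
  for (k in ANNOTATION_KEYS) {
    if (is.null(variants[[k]])) variants[[k]] <- rep(NA_real_, n)
  }
  variants$vclass <- variant_class(variants$ref, variants$alt)
  colnames(gt) <- colnames(ad_ref) <- colnames(ad_alt) <- colnames(dp) <- samples
  structure(list(variants = variants, gt = gt, ad_ref = ad_ref,
                 ad_alt = ad_alt, dp = dp, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("Multi-sample variant set:", nrow(x$variants), "variants,",
      length(x$samples), "samples\n")
  if (nrow(x$variants) > 0) {
    cat("  classes:", paste(names(table(x$variants$vclass)),
                            table(x$variants$vclass), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.variant_set <- function(x) c(nrow(x$variants), length(x$samples))

# subset a variant_set by row index
subset_variant_set <- function(vs, idx) {
  variant_set(vs$variants[idx, , drop = FALSE],
              vs$gt[idx, , drop = FALSE],
              vs$ad_ref[idx, , drop = FALSE],
              vs$ad_alt[idx, , drop = FALSE],
              vs$dp[idx, , drop = FALSE],
              vs$samples)
}

#' Read a multi-sample VCF of small variants
#'
#' Parses a VCF v4.x file (plain text or gzipped), splits multi-allelic
#' records into bi-allelic ones with per-alternate AD slices, maps the
#' genotype of each sample onto the single retained ALT allele, and
#' extracts the six site annotations used by the hard filters (absent
#' annotations are kept as `NA`, never coerced to zero).  Chromosome names
#' are normalized to the "chr"-prefixed convention.
#'
#' @param path path to the VCF file.
#' @return a [variant_set()].
#' @seealso [write_variant_vcf()] for the inverse operation.
#' @export
read_multisample_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  check_vcf_layout(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  n0 <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  if (n0 == 0) {
    e_chr <- matrix(character(0), 0, length(samples))
    e_int <- matrix(integer(0), 0, length(samples))
    return(variant_set(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      e_chr, e_int, e_int, e_int, samples))
  }
  ann <- lapply(ANNOTATION_KEYS, function(k) {
    suppressWarnings(vcfR::extract.info(v, element = k, as.numeric = TRUE))
  })
  names(ann) <- ANNOTATION_KEYS
  gt0 <- vcfR::extract.gt(v, element = "GT")
  ad0 <- vcfR::extract.gt(v, element = "AD")
  dp0 <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                           as.numeric = TRUE))
  if (is.null(gt0)) stop("VCF FORMAT must contain GT: ", path)

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_of <- rep(seq_len(n0), n_alt)        # original record per split row
  alt_idx <- unlist(lapply(n_alt, seq_len))  # which ALT within the record
  alts <- unlist(alt_list)

  variants <- data.frame(
    chrom = normalize_chrom(fix[row_of, "CHROM"]),
    pos = as.integer(fix[row_of, "POS"]),
    ref = fix[row_of, "REF"],
    alt = alts,
    stringsAsFactors = FALSE)
  for (k in ANNOTATION_KEYS) variants[[k]] <- ann[[k]][row_of]
  bad <- !grepl("^[ACGT]+$", variants$ref) | !grepl("^[ACGT]+$", variants$alt)
  if (any(bad)) {
    variants <- variants[!bad, , drop = FALSE]
    row_of2 <- row_of[!bad]; alt_idx <- alt_idx[!bad]
  } else row_of2 <- row_of

  ns <- length(samples)
  nr <- nrow(variants)
  gt <- matrix(NA_character_, nr, ns)
  adr <- ada <- dpm <- matrix(NA_integer_, nr, ns)
  if (ns > 0 && nr > 0) {
    for (j in seq_len(ns)) {
      gtj <- gt0[row_of2, j]
      tok <- strsplit(gtj, "[/|]")
      # number of alleles equal to this record's ALT index
      nalt_allele <- mapply(function(tk, k) {
        if (length(tk) == 0 || any(tk == ".") || all(is.na(tk))) return(NA_integer_)
        sum(tk == as.character(k))
      }, tok, alt_idx)
      gt[, j] <- ifelse(is.na(nalt_allele), NA_character_,
                        c("0/0", "0/1", "1/1")[nalt_allele + 1L])
      adj <- strsplit(ifelse(is.na(ad0[row_of2, j]), "", ad0[row_of2, j]),
                      ",", fixed = TRUE)
      adr[, j] <- vapply(adj, function(a)
        if (length(a) >= 1) suppressWarnings(as.integer(a[1])) else NA_integer_,
        integer(1))
      ada[, j] <- mapply(function(a, k)
        if (length(a) >= k + 1) suppressWarnings(as.integer(a[k + 1])) else NA_integer_,
        adj, alt_idx)
      dpm[, j] <- as.integer(dp0[row_of2, j])
    }
  }
  variant_set(variants, gt, adr, ada, dpm, samples)
}

# Structural validation of a VCF file: header line present, constant
# column count on data lines.  Errors name the offending line.
check_vcf_layout <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1) {
    stop("malformed VCF header (no #CHROM line): ", path)
  }
  ncol_expect <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(data_idx)) {
    nf <- nchar(lines[data_idx]) - nchar(gsub("\t", "", lines[data_idx],
                                              fixed = TRUE)) + 1L
    bad <- data_idx[nf != ncol_expect]
    if (length(bad)) {
      stop("VCF parse error at line ", bad[1], " of ", path,
           ": expected ", ncol_expect, " columns, found ",
           nf[match(bad[1], data_idx)])
    }
  }
  invisible(TRUE)
}

#' Write a variant set as a multi-sample VCF
#'
#' Emits a VCF v4.2 file with FORMAT `GT:AD:DP` and the six hard-filter
#' site annotations in INFO (absent annotations are omitted, not written
#' as zero).  Round-trips with [read_multisample_vcf()] for `chrom`, `pos`,
#' `ref`, `alt`, GT, AD and DP.
#'
#' @param vs a [variant_set()].
#' @param path output file path.
#' @param contigs optional named numeric vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vs, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   ANNOTATION_KEYS, ANNOTATION_KEYS),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$samples), collapse = "\t"))
  va <- vs$variants
  n <- nrow(va)
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  info <- vapply(seq_len(n), function(i) {
    vals <- unlist(va[i, ANNOTATION_KEYS])
    keep <- !is.na(vals)
    if (!any(keep)) "." else
      paste(sprintf("%s=%s", ANNOTATION_KEYS[keep],
                    format_num(vals[keep])), collapse = ";")
  }, character(1))
  fmt_call <- function(j) {
    gt <- vs$gt[, j]
    ad <- ifelse(is.na(vs$ad_ref[, j]) & is.na(vs$ad_alt[, j]), ".",
                 paste0(na_dot(vs$ad_ref[, j]), ",", na_dot(vs$ad_alt[, j])))
    dp <- na_dot(vs$dp[, j])
    paste0(ifelse(is.na(gt), "./.", gt), ":", ad, ":", dp)
  }
  calls <- vapply(seq_along(vs$samples), fmt_call, character(n))
  if (n == 1) calls <- matrix(calls, nrow = 1)
  body <- paste(va$chrom, va$pos, ".", va$ref, va$alt, ".", ".", info,
                "GT:AD:DP", sep = "\t")
  if (length(vs$samples) > 0) {
    body <- paste(body, apply(calls, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 6)
  sub("^\\s+", "", out)
}

na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))

#' Read an SV-caller VCF of complex indels
#'
#' Consumes the output dialect of structural-variant callers (LUMPY /
#' SVTyper style): `SVTYPE` and `END` and `SU` (number of pieces of
#' supporting evidence across samples) in INFO, a numeric QUAL column, and
#' per-sample `GT` (optionally `DP`).
#'
#' @param path path to the SV VCF.
#' @return an object of class `"sv_set"`: a list with `records`
#'   (data.frame `chrom`, `start`, `end` -- half-open 0-based interval --
#'   `svtype`, `qual`, `su`), `gt` and `dp` matrices, and `samples`.
#' @export
read_sv_vcf <- function(path) {
  if (!file.exists(path)) stop("SV VCF file not found: ", path)
  check_vcf_layout(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  n <- nrow(fix)
  pos <- as.integer(fix[, "POS"])
  end1 <- suppressWarnings(vcfR::extract.info(v, "END", as.numeric = TRUE))
  svtype <- vcfR::extract.info(v, "SVTYPE")
  su <- suppressWarnings(vcfR::extract.info(v, "SU", as.numeric = TRUE))
  recs <- data.frame(
    chrom = normalize_chrom(fix[, "CHROM"]),
    start = pos - 1L,                    # 0-based half-open
    end = as.integer(end1),
    svtype = ifelse(is.na(svtype), "other", svtype),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    su = as.integer(su),
    stringsAsFactors = FALSE)
  if (n > 0 && any(!is.na(recs$end) & recs$end <= recs$start)) {
    stop("SV record with end <= start in ", path)
  }
  gt <- if (n > 0 && length(samples)) vcfR::extract.gt(v, "GT") else
    matrix(NA_character_, n, length(samples))
  dp <- if (n > 0 && length(samples))
    suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE)) else
      matrix(NA_real_, n, length(samples))
  if (is.null(dp)) dp <- matrix(NA_real_, n, length(samples))
  gt <- matrix(as.character(gt), n, length(samples),
               dimnames = list(NULL, samples))
  dp <- matrix(as.numeric(dp), n, length(samples),
               dimnames = list(NULL, samples))
  structure(list(records = recs, gt = gt, dp = dp, samples = samples),
            class = "sv_set")
}

#' @export
print.sv_set <- function(x, ...) {
  cat("Complex-indel (SV) set:", nrow(x$records), "records,",
      length(x$samples), "samples\n")
  invisible(x)
}
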