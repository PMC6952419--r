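# Mutational spectra and nonparametric group statistics.

SUB_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                 "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")
SUB_CLASSES_COLLAPSED <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a single-nucleotide substitution
#'
#' Maps a REF/ALT base pair to one of the 12 directional substitution
#' classes, or (with `collapse = TRUE`) to one of the 6 pyrimidine-centred
#' classes, where purine-reference substitutions are mapped to the
#' reverse complement (e.g. G>A becomes C>T).
#'
#' @param ref,alt character vectors of single bases (A/C/G/T), `ref != alt`.
#' @param collapse collapse to the 6 pyrimidine-reference classes.
#' @return factor of class labels (levels in fixed spectrum order).
#' @examples
#' classify_substitution("G", "A", collapse = TRUE)  # C>T
#' @export
classify_substitution <- function(ref, alt, collapse = FALSE) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  if (length(ref) == 0) {
    return(factor(character(0),
                  levels = if (collapse) SUB_CLASSES_COLLAPSED else
                    SUB_CLASSES))
  }
  ok <- ref %in% BASES & alt %in% BASES
  if (!all(ok)) stop("ref and alt must be single bases A/C/G/T")
  if (any(ref == alt)) stop("ref must differ from alt")
  if (collapse) {
    pur <- ref %in% c("A", "G")
    r <- ifelse(pur, COMPLEMENT[ref], ref)
    a <- ifelse(pur, COMPLEMENT[alt], alt)
    factor(paste0(r, ">", a), levels = SUB_CLASSES_COLLAPSED)
  } else {
    factor(paste0(ref, ">", alt), levels = SUB_CLASSES)
  }
}

#' Tabulate per-sample mutational spectra
#'
#' Counts de novo SNVs per sample over the 12 directional substitution
#' classes (or the 6 collapsed classes).  Row sums equal each sample's
#' de novo SNV count.
#'
#' @param snvs data.frame of SNVs with columns `sample`, `ref`, `alt`
#'   (e.g. the `snvs` element of a `"denovo_cohort"`).
#' @param samples optional character vector fixing the row set/order
#'   (samples with no SNVs get zero rows).
#' @param collapse use the 6 pyrimidine-reference classes.
#' @return integer matrix, samples x classes.
#' @export
spectrum_table <- function(snvs, samples = NULL, collapse = FALSE) {
  if (is.null(samples)) samples <- sort(unique(snvs$sample))
  cls <- classify_substitution(snvs$ref, snvs$alt, collapse = collapse)
  tab <- table(factor(snvs$sample, levels = samples), cls)
  m <- matrix(as.integer(tab), nrow = length(samples),
              dimnames = list(samples, colnames(tab)))
  m
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' U is computed from midranks.  The p-value is exact (by complete
#' enumeration of rank assignments) when `n1 + n2 <= exact_limit` and
#' there are no ties, otherwise a normal approximation with tie and
#' continuity correction is used.  The two-sided p-value doubles the
#' smaller one-sided tail, capped at 1.
#'
#' @param x,y non-empty numeric vectors (e.g. per-mouse de novo counts).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact enumeration;
#'   the default `NULL` chooses automatically.  Exact enumeration with
#'   ties is not supported and falls back to the approximation.
#' @param exact_limit maximum `n1 + n2` for the automatic exact path.
#' @param correct apply the continuity correction in the normal
#'   approximation.
#' @return an object of class `"htest"` with the U statistic (for `x`)
#'   and the two-sided p-value.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p.value  # 1/3
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_limit = 12,
                           correct = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  ties <- anyDuplicated(c(x, y)) > 0
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- if (is.null(exact)) (n <= exact_limit && !ties) else
    (exact && !ties)
  if (use_exact) {
    # enumerate all C(n, n1) assignments of ranks 1..n to sample x
    combs <- utils::combn(n, n1)
    u_all <- colSums(matrix(seq_len(n)[combs], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p_lower <- mean(u_all <= u)
    p_upper <- mean(u_all >= u)
    p <- min(1, 2 * min(p_lower, p_upper))
    method <- "Exact Mann-Whitney U test (full enumeration)"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      if (correct) z <- z - sign(z) * 0.5
      z <- z / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- paste0("Mann-Whitney U test (normal approximation",
                     if (correct) " with continuity correction", ")")
  }
  structure(list(statistic = c(U = u), p.value = p, method = method,
                 alternative = "two.sided",
                 data.name = paste(deparse1(substitute(x)), "and",
                                   deparse1(substitute(y)))),
            class = "htest")
}

#' Kruskal-Wallis rank test
#'
#' H is computed via the rank-sum formula with tie correction; the
#' p-value comes from the chi-squared distribution with `k - 1` degrees
#' of freedom.  When every observation is tied the statistic is
#' degenerate and `H = 0`, `p = 1` is reported.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return an object of class `"htest"` with statistic `H` and p-value.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$statistic  # H = 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("groups must be a list of >= 2 samples")
  }
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  all_x <- unlist(groups)
  if (anyNA(all_x)) stop("missing values are not supported")
  n <- length(all_x)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(all_x)
  rsum <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
  tie_tab <- table(all_x)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  df <- length(groups) - 1
  if (corr <= 0) {
    h <- 0
    p <- 1
  } else {
    h <- h / corr
    p <- stats::pchisq(h, df = df, lower.tail = FALSE)
  }
  structure(list(statistic = c(H = h), parameter = c(df = df),
                 p.value = p,
                 method = "Kruskal-Wallis rank test (tie-corrected)",
                 data.name = "groups"),
            class = "htest")
}

#' Group summary statistics and nonparametric comparisons
#'
#' Computes per-group mean, SD, min and max of per-offspring de novo
#' variant counts, a Kruskal-Wallis test across all groups, and all
#' pairwise Mann-Whitney U tests, plus boxplot tuples in the
#' mean +/- SD convention (center = mean, box limits = mean +/- SD,
#' whiskers = min/max).
#'
#' @param counts either a `"denovo_cohort"` (counts are derived with
#'   [denovo_counts()]) or a data.frame with columns `sample`, `group`
#'   and the count column named by `what`.
#' @param what which count to compare: `"snv"` or `"indel"` (column
#'   `n_snv` / `n_indel`).
#' @param p_adjust multiple-testing correction for the pairwise p-values
#'   (`"none"` by default; any method of [stats::p.adjust()] may be
#'   given, e.g. `"bonferroni"`).
#' @param exact_limit passed to [mann_whitney_u()].
#' @return an object of class `"group_comparison"`: list with `stats`
#'   (per-group summaries), `kruskal` (`htest`), `pairwise` (data.frame
#'   of group pairs, U and two-sided p), `boxplot` (plotting tuples) and
#'   the per-sample `counts` used.  With a single group the tests are
#'   skipped with a warning.
#' @export
summarize_groups <- function(counts, what = c("snv", "indel"),
                             p_adjust = "none", exact_limit = 12) {
  what <- match.arg(what)
  if (inherits(counts, "denovo_cohort")) counts <- denovo_counts(counts)
  col <- paste0("n_", what)
  if (!all(c("sample", "group", col) %in% names(counts))) {
    stop("counts must have columns sample, group, ", col)
  }
  counts <- counts[!is.na(counts$group), , drop = FALSE]
  groups <- split(counts[[col]], counts$group)
  if (any(lengths(groups) == 0)) stop("group with zero members")
  stats_df <- data.frame(
    group = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    min = vapply(groups, min, numeric(1)),
    max = vapply(groups, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  boxplot_df <- data.frame(
    group = stats_df$group,
    center = stats_df$mean,
    box_lower = stats_df$mean - stats_df$sd,
    box_upper = stats_df$mean + stats_df$sd,
    whisker_min = stats_df$min,
    whisker_max = stats_df$max,
    stringsAsFactors = FALSE)
  kw <- NULL
  pairwise <- NULL
  if (length(groups) < 2) {
    warning("only one group present; tests skipped")
  } else {
    kw <- kruskal_wallis(groups)
    pairs <- utils::combn(names(groups), 2)
    pairwise <- data.frame(
      group1 = pairs[1, ], group2 = pairs[2, ],
      U = NA_real_, p.value = NA_real_, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(pairs))) {
      mw <- mann_whitney_u(groups[[pairs[1, j]]], groups[[pairs[2, j]]],
                           exact_limit = exact_limit)
      pairwise$U[j] <- unname(mw$statistic)
      pairwise$p.value[j] <- mw$p.value
    }
    pairwise$p.adjusted <- stats::p.adjust(pairwise$p.value,
                                           method = p_adjust)
  }
  structure(list(what = what, stats = stats_df, kruskal = kw,
                 pairwise = pairwise, boxplot = boxplot_df,
                 counts = counts[, c("sample", "group", col)]),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of per-mouse de novo %s counts\n",
              toupper(x$what)))
  s <- x$stats
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s n=%2d  mean %7.2f +/- %6.2f  [%g, %g]\n",
                s$group[i], s$n[i], s$mean[i], s$sd[i], s$min[i], s$max[i]))
  }
  if (!is.null(x$kruskal)) {
    cat(sprintf("  Kruskal-Wallis: H = %.4g, p = %.4g\n",
                unname(x$kruskal$statistic), x$kruskal$p.value))
    cat("  Pairwise Wilcoxon rank-sum / Mann-Whitney U (two-sided):\n")
    p <- x$pairwise
    for (j in seq_len(nrow(p))) {
      cat(sprintf("    %s vs %s: U = %g, p = %.4g\n",
                  p$group1[j], p$group2[j], p$U[j], p$p.value[j]))
    }
  }
  invisible(x)
}
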