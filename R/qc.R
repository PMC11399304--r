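#' Quality-control thresholds
#'
#' One object holding every variant- and sample-level filter threshold the
#' pipeline applies.  Defaults are the heritability-set values; use
#' `mode = "gwas"` for the more stringent GWAS minor-allele-frequency floor.
#'
#' @param maf_min minimum minor allele frequency (default 3e-4; 1e-3 in
#'   `"gwas"` mode).
#' @param hwe_p_min Hardy-Weinberg equilibrium p-value floor (variants below
#'   are removed).
#' @param variant_missing_max maximum per-variant missing-call proportion.
#' @param sample_missing_max maximum per-sample genotype missingness.
#' @param relatedness_max GRM off-diagonal ceiling used by
#'   [prune_relatedness()].
#' @param icv_sd intracranial-volume outlier bound in within-sex SD units.
#' @param euler_min minimum acceptable Euler number (image quality).
#' @param pheno_sd phenotype outlier bound in SD units.
#' @param biallelic_only drop variants flagged non-biallelic.
#' @param mode `"heritability"` or `"gwas"`; only changes the `maf_min`
#'   default.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = NULL, hwe_p_min = 1e-6,
                          variant_missing_max = 0.05,
                          sample_missing_max = 0.1,
                          relatedness_max = 0.05,
                          icv_sd = 4, euler_min = -217, pheno_sd = 5,
                          biallelic_only = TRUE,
                          mode = c("heritability", "gwas")) {
  mode <- match.arg(mode)
  if (is.null(maf_min)) maf_min <- if (mode == "gwas") 1e-3 else 3e-4
  structure(list(maf_min = check_prob(maf_min, "maf_min"),
                 hwe_p_min = check_prob(hwe_p_min, "hwe_p_min"),
                 variant_missing_max = check_prob(variant_missing_max,
                                                  "variant_missing_max"),
                 sample_missing_max = check_prob(sample_missing_max,
                                                 "sample_missing_max"),
                 relatedness_max = as.numeric(relatedness_max),
                 icv_sd = as.numeric(icv_sd),
                 euler_min = as.numeric(euler_min),
                 pheno_sd = as.numeric(pheno_sd),
                 biallelic_only = isTRUE(biallelic_only),
                 mode = mode),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the HWE expectations at the sample allele frequency.  Monomorphic input
#' (or zero expected counts) returns `chi2 = 0, p = 1`.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectorized; non-negative).
#' @return A list with numeric vectors `chi2` and `p`.
#' @examples
#' hwe_chi2(10, 10, 10)  # chi2 = 10/3, p ~ 0.0679
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0, na.rm = TRUE)) {
    stop_invalid("genotype counts must be non-negative")
  }
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1, na.rm = TRUE)) stop_invalid("need at least one genotype")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e_AA <- n * p^2
  e_Aa <- 2 * n * p * q
  e_aa <- n * q^2
  mono <- p == 0 | p == 1
  chi2 <- ifelse(mono, 0,
                 (n_AA - e_AA)^2 / e_AA +
                 (n_Aa - e_Aa)^2 / e_Aa +
                 (n_aa - e_aa)^2 / e_aa)
  list(chi2 = chi2, p = ifelse(mono, 1, stats::pchisq(chi2, 1, lower.tail = FALSE)))
}

# Per-variant QC statistics on a sample subset.  X-chromosome HWE is
# evaluated in females only (males are hemizygous).
variant_stats <- function(panel, samples) {
  d <- panel$dosage[samples, , drop = FALSE]
  sex <- panel$fam$sex[samples]
  xv <- is_x_chrom(panel$map$chrom)
  m <- ncol(d)
  miss <- colMeans(is.na(d))
  freq <- allele_freq(panel, samples)
  maf <- pmin(freq, 1 - freq)
  hwe_p <- rep(1, m)
  for (j in seq_len(m)) {
    g <- if (xv[j]) d[sex == 2L, j] else d[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) next
    hwe_p[j] <- hwe_chi2(sum(g == 2), sum(g == 1), sum(g == 0))$p
  }
  data.frame(maf = maf, hwe_p = hwe_p, missing = miss)
}

#' Variant-level quality control
#'
#' Applies, in a fixed order, the biallelic, minor-allele-frequency,
#' Hardy-Weinberg and missingness filters.  X-chromosome variants are
#' evaluated in each sex separately and retained only if they pass in both
#' sexes (HWE in females only); autosomal variants are evaluated on the
#' combined sample.
#'
#' Imputation INFO scores are never computed; when the panel's `map`
#' carries an `info` column (a pass-through from upstream imputation),
#' variants with `info < info_min` are removed first.
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @param per_sex_x evaluate X-chromosome filters per sex (default `TRUE`).
#' @param info_min imputation INFO floor applied only if `panel$map$info`
#'   exists.
#' @return A list with the filtered `panel` and a `report` (class
#'   `qc_report`) recording the count removed by each filter in application
#'   order.
#' @export
filter_variants <- function(panel, thresholds = qc_thresholds(),
                            per_sex_x = TRUE, info_min = 0.3) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(thresholds, "qc_thresholds"))
  xv <- is_x_chrom(panel$map$chrom)
  male <- panel$fam$sex == 1L
  all_s <- seq_len(n_samples(panel))
  stats_all <- variant_stats(panel, all_s)
  use_sex <- per_sex_x && any(xv) && any(male) && !all(male)
  if (use_sex) {
    stats_m <- variant_stats(panel, which(male))
    stats_f <- variant_stats(panel, which(!male))
  }
  # a variant passes a criterion if it passes on every evaluation stratum
  pass_on <- function(fn) {
    ok <- fn(stats_all)
    if (use_sex) {
      ok_x <- fn(stats_m) & fn(stats_f)
      ok[xv] <- ok_x[xv]
    }
    ok[is.na(ok)] <- FALSE
    ok
  }
  keep <- rep(TRUE, n_variants(panel))
  steps <- list(
    info = if (is.null(panel$map$info)) TRUE else panel$map$info >= info_min,
    biallelic = if (thresholds$biallelic_only) panel$map$biallelic else TRUE,
    maf = pass_on(function(s) !is.na(s$maf) & s$maf >= thresholds$maf_min),
    hwe = pass_on(function(s) s$hwe_p >= thresholds$hwe_p_min),
    missingness = pass_on(function(s) s$missing <= thresholds$variant_missing_max)
  )
  removed <- integer(length(steps))
  names(removed) <- names(steps)
  for (k in names(steps)) {
    drop_k <- keep & !steps[[k]]
    removed[[k]] <- sum(drop_k)
    keep <- keep & steps[[k]]
  }
  if (!any(keep)) warning("all variants removed by QC filters")
  report <- structure(list(kind = "variant",
                           n_in = n_variants(panel), n_out = sum(keep),
                           removed = as.list(removed),
                           order = names(steps),
                           thresholds = unclass(thresholds)),
                      class = "qc_report")
  out <- if (any(keep)) subset_panel(panel, variants = which(keep)) else NULL
  list(panel = out, report = report)
}

#' Sample-level quality control
#'
#' Removes, in order: samples with Euler number below `euler_min`; samples
#' whose intracranial volume lies more than `icv_sd` within-sex SDs from the
#' within-sex mean (sex-group statistics computed on the post-Euler set);
#' samples with genotype missingness above `sample_missing_max` (when a
#' panel is supplied); and samples with any listed phenotype beyond
#' `pheno_sd` SDs of its mean.  Set a threshold to `NA` to disable its
#' filter.
#'
#' @param pheno data.frame with one row per sample, an `iid` column, and the
#'   columns named by `euler_col` / `icv_col` / `pheno_cols` as needed.
#' @param panel optional [genotype_panel()] for the missingness filter.
#' @param thresholds a [qc_thresholds()].
#' @param euler_col,icv_col column names (set to `NULL` to skip the filter).
#' @param pheno_cols phenotype columns for the outlier filter (default none).
#' @return A list with `kept` (character iids) and a `qc_report`.
#' @export
filter_samples <- function(pheno, panel = NULL, thresholds = qc_thresholds(),
                           euler_col = "euler", icv_col = "icv",
                           pheno_cols = NULL) {
  stopifnot(is.data.frame(pheno), "iid" %in% names(pheno))
  need_col <- function(col, what) {
    if (!col %in% names(pheno)) {
      stop_invalid("column '%s' required for the %s filter is missing", col, what)
    }
  }
  keep <- rep(TRUE, nrow(pheno))
  removed <- list()
  if (!is.null(euler_col) && !is.na(thresholds$euler_min)) {
    need_col(euler_col, "Euler-number")
    bad <- pheno[[euler_col]] < thresholds$euler_min
    removed$euler <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (!is.null(icv_col) && !is.na(thresholds$icv_sd)) {
    need_col(icv_col, "intracranial-volume")
    need_col("sex", "intracranial-volume")
    bad <- rep(FALSE, nrow(pheno))
    for (s in unique(pheno$sex)) {
      grp <- keep & pheno$sex == s          # post-Euler statistics
      mu <- mean(pheno[[icv_col]][grp])
      sdv <- stats::sd(pheno[[icv_col]][grp])
      bad[grp] <- abs(pheno[[icv_col]][grp] - mu) > thresholds$icv_sd * sdv
    }
    removed$icv <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (!is.null(panel) && !is.na(thresholds$sample_missing_max)) {
    miss <- rowMeans(is.na(panel$dosage))[match(pheno$iid, panel$fam$iid)]
    bad <- !is.na(miss) & miss > thresholds$sample_missing_max
    removed$sample_missingness <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (!is.null(pheno_cols) && !is.na(thresholds$pheno_sd)) {
    bad <- rep(FALSE, nrow(pheno))
    for (col in pheno_cols) {
      need_col(col, "phenotype-outlier")
      v <- pheno[[col]]
      mu <- mean(v[keep], na.rm = TRUE)
      sdv <- stats::sd(v[keep], na.rm = TRUE)
      bad <- bad | (!is.na(v) & abs(v - mu) > thresholds$pheno_sd * sdv)
    }
    removed$phenotype_outlier <- sum(bad & keep)
    keep <- keep & !bad
  }
  report <- structure(list(kind = "sample", n_in = nrow(pheno),
                           n_out = sum(keep), removed = removed,
                           order = names(removed),
                           thresholds = unclass(thresholds)),
                      class = "qc_report")
  list(kept = pheno$iid[keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (%s level): %d in -> %d out\n", x$kind, x$n_in, x$n_out))
  for (k in x$order) cat(sprintf("  %-20s removed %d\n", k, x$removed[[k]]))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` from [filter_variants()] or
#'   [filter_samples()].
#' @param file output path.
#' @export
write_qc_report <- function(report, file) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
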