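#' Residualize a trait on covariates
#'
#' Ordinary least-squares residuals of the trait on an intercept plus the
#' covariates (plus, for regional traits, the corresponding global measure),
#' computed within each sex group separately when `sex` is given.  The
#' design must be full rank; a rank-deficient design raises an error naming
#' the collinear columns.
#'
#' @param y numeric trait vector.
#' @param covariates numeric matrix (or data.frame) of covariates; may be
#'   `NULL`, in which case residuals are the (groupwise) mean-centered
#'   trait.
#' @param global_measure optional numeric vector appended to the covariates
#'   (the global-phenotype correction for regional traits).
#' @param sex optional group vector; residualization runs within each level.
#' @return Numeric vector of residuals, same length/order as `y`.
#' @export
residualize <- function(y, covariates = NULL, global_measure = NULL,
                        sex = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  Xc <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(global_measure)) {
    Xc <- cbind(Xc, global = as.numeric(global_measure))
  }
  X <- build_design(n, Xc)
  colnames(X)[1] <- "(intercept)"
  groups <- if (is.null(sex)) list(seq_len(n)) else split(seq_len(n), sex)
  out <- numeric(n)
  for (idx in groups) {
    Xi <- X[idx, , drop = FALSE]
    q <- qr(Xi)
    if (q$rank < ncol(Xi)) {
      bad <- colnames(Xi)[q$pivot[(q$rank + 1):ncol(Xi)]]
      stop_invalid("rank-deficient design; collinear column(s): %s",
                   paste(bad, collapse = ", "))
    }
    out[idx] <- qr.resid(q, y[idx])
  }
  out
}

#' Sex-stratified per-variant linear association
#'
#' For every variant, ordinary least squares of the (pre-adjusted) trait on
#' allele dosage plus an intercept and the supplied covariates, restricted
#' to one sex group.  Missing dosages drop samples variant-wise (complete
#' cases, PLINK behavior).  Male X dosages are recoded 0/2 (the full
#' dosage-compensation coding and PLINK's default additive X model).
#' Two-sided p-values use the t distribution with `n - k - 2` df (k =
#' number of covariates).
#'
#' @param panel a QC'd [genotype_panel()].
#' @param trait numeric vector aligned with the panel samples (typically the
#'   output of [residualize()]).
#' @param covariates optional numeric matrix aligned with the panel samples
#'   (e.g. ancestry principal components).
#' @param sex_group `"male"` or `"female"`.
#' @return data.frame with PLINK2-flavoured columns: `CHROM`, `POS`, `ID`,
#'   `A1`, `A2`, `OBS_CT`, `BETA`, `SE`, `T_STAT`, `P`, plus `STATUS`
#'   (`"ok"`, `"untestable"` for zero-variance dosages — flagged, never
#'   silently dropped — or `"exact_fit"` when the residual variance is 0).
#' @export
run_stratified_gwas <- function(panel, trait, covariates = NULL,
                                sex_group = c("male", "female")) {
  sex_group <- match.arg(sex_group)
  stopifnot(inherits(panel, "genotype_panel"))
  trait <- as.numeric(trait)
  if (length(trait) != n_samples(panel)) {
    stop_invalid("trait must have one value per panel sample")
  }
  sel <- panel$fam$sex == if (sex_group == "male") 1L else 2L
  if (!any(sel)) stop_invalid("no %s samples in panel", sex_group)
  d <- panel$dosage[sel, , drop = FALSE]
  xv <- is_x_chrom(panel$map$chrom)
  if (sex_group == "male" && any(xv)) d[, xv] <- 2 * d[, xv]
  y <- trait[sel]
  Xc <- if (is.null(covariates)) NULL else as.matrix(covariates)[sel, , drop = FALSE]
  k <- if (is.null(Xc)) 0L else ncol(Xc)
  n <- nrow(d)
  m <- ncol(d)
  beta <- se <- tstat <- pval <- rep(NA_real_, m)
  obs_ct <- integer(m)
  status <- rep("ok", m)
  df <- n - k - 2L
  if (!anyNA(d) && df > 0L) {
    # fast path: shared complete-case design, Frisch-Waugh partialling
    q <- qr(build_design(n, Xc))
    if (q$rank < ncol(build_design(n, Xc))) stop_invalid("singular covariate design")
    ry <- qr.resid(q, y)
    rd <- qr.resid(q, d)
    sxx <- colSums(rd^2)
    sxy <- drop(crossprod(rd, ry))
    syy <- sum(ry^2)
    obs_ct[] <- n
    testable <- sxx > n * 1e-12
    beta[testable] <- sxy[testable] / sxx[testable]
    rss <- pmax(0, syy - beta^2 * sxx)
    exact <- testable & rss <= 1e-12 * max(syy, 1)
    se[testable] <- sqrt(rss[testable] / df / sxx[testable])
    tstat[testable] <- beta[testable] / se[testable]
    pval[testable] <- 2 * stats::pt(-abs(tstat[testable]), df)
    status[!testable] <- "untestable"
    status[exact] <- "exact_fit"
    pval[exact] <- 0
    tstat[exact] <- Inf * sign(beta[exact])
  } else {
    for (j in seq_len(m)) {
      cc <- !is.na(d[, j])
      nj <- sum(cc)
      obs_ct[j] <- nj
      dfj <- nj - k - 2L
      xj <- d[cc, j]
      if (dfj < 1L || stats::var(xj) <= 1e-12) {
        status[j] <- "untestable"
        next
      }
      Xf <- cbind(build_design(nj, if (is.null(Xc)) NULL else Xc[cc, , drop = FALSE]),
                  dosage = xj)
      q <- qr(Xf)
      if (q$rank < ncol(Xf)) {
        status[j] <- "untestable"
        next
      }
      coefs <- qr.coef(q, y[cc])
      res <- qr.resid(q, y[cc])
      rss <- sum(res^2)
      xtxi <- chol2inv(qr.R(q))
      beta[j] <- coefs[["dosage"]]
      if (rss <= 1e-12 * max(sum(y[cc]^2), 1)) {
        status[j] <- "exact_fit"
        se[j] <- 0
        tstat[j] <- Inf * sign(beta[j])
        pval[j] <- 0
        next
      }
      se[j] <- sqrt(rss / dfj * xtxi[ncol(Xf), ncol(Xf)])
      tstat[j] <- beta[j] / se[j]
      pval[j] <- 2 * stats::pt(-abs(tstat[j]), dfj)
    }
  }
  data.frame(CHROM = panel$map$chrom, POS = panel$map$pos,
             ID = panel$map$id, A1 = panel$map$a1, A2 = panel$map$a2,
             OBS_CT = obs_ct, BETA = beta, SE = se, T_STAT = tstat,
             P = pval, STATUS = status, stringsAsFactors = FALSE)
}

#' Write GWAS records as a PLINK2-style TSV
#'
#' @param records data.frame from [run_stratified_gwas()].
#' @param file output path.
#' @export
write_gwas_tsv <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
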