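#' Sex-difference z test for paired estimates
#'
#' For a male/female pair of estimates with standard errors,
#' `z = (est_m - est_f) / sqrt(se_m^2 + se_f^2)` and
#' `p = 2 (1 - Phi(|z|))`.  Applies identically to heritability pairs and to
#' GWAS effect-size pairs.  Vectorized.
#'
#' @param est_m,est_f per-sex estimates.
#' @param se_m,se_f per-sex standard errors (must be > 0).
#' @return list with numeric vectors `z` and `p`.
#' @examples
#' zdiff(0.30, 0.20, 0.05, 0.05)   # z = 1.414, p = 0.157
#' @export
zdiff <- function(est_m, est_f, se_m, se_f) {
  if (any(!is.finite(se_m) | !is.finite(se_f) | se_m <= 0 | se_f <= 0)) {
    stop_invalid("standard errors must be finite and positive")
  }
  z <- (est_m - est_f) / sqrt(se_m^2 + se_f^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni multiple-testing threshold
#'
#' @param base_alpha base significance level (e.g. 0.05, or the genome-wide
#'   5e-8).
#' @param n_tests number of tests corrected for (>= 1).
#' @return `base_alpha / n_tests`.
#' @examples
#' mtc_threshold(0.05, 360)    # 1.4e-4: regional heritability comparisons
#' mtc_threshold(5e-8, 361)    # 1.4e-10: "strict" cortical SNP threshold
#' mtc_threshold(5e-8, 23)     # 2.17e-9: "strict" subcortical threshold
#' @export
mtc_threshold <- function(base_alpha, n_tests) {
  n_tests <- check_count(n_tests, "n_tests", min = 1L)
  check_prob(base_alpha, "base_alpha", lo_open = TRUE) / n_tests
}

#' Catalog of the neuroanatomical phenotype panel
#'
#' Enumerates the phenotypes the pipeline screens: one entry per cortical
#' region per morphometric class (gray-matter volume, surface area, cortical
#' thickness), plus the subcortical volumes and the global measures.  The
#' defaults reproduce the bilateral 180-regions-per-hemisphere cortical
#' parcellation (360 regions), 23 subcortical volumes, and 3 global
#' measures, i.e. 1106 phenotypes.
#'
#' @param n_regions cortical regions per class.
#' @param classes cortical morphometric classes.
#' @param n_subcortical subcortical volumes.
#' @param n_global global measures.
#' @return data.frame with columns `phenotype` and `class`.
#' @export
phenotype_catalog <- function(n_regions = 360L,
                              classes = c("GMV", "SA", "CT"),
                              n_subcortical = 23L, n_global = 3L) {
  n_regions <- check_count(n_regions, "n_regions")
  n_subcortical <- check_count(n_subcortical, "n_subcortical")
  n_global <- check_count(n_global, "n_global")
  cortical <- expand.grid(region = seq_len(n_regions), class = classes,
                          stringsAsFactors = FALSE)
  data.frame(
    phenotype = c(paste0(cortical$class, "_region", cortical$region),
                  paste0("subcortical", seq_len(n_subcortical)),
                  paste0("global", seq_len(n_global))),
    class = c(cortical$class, rep("subcortical", n_subcortical),
              rep("global", n_global)),
    stringsAsFactors = FALSE)
}

#' Paired cross-region tests of a per-sex statistic
#'
#' Classical paired two-tailed t test on male-minus-female differences
#' across regions, with the Wilcoxon signed-rank test as the nonparametric
#' companion (exact for n <= 25, normal approximation with continuity
#' correction above).
#'
#' @param values_m,values_f per-region vectors (equal length >= 2).
#' @return list with `t`, `df`, `mean_diff`, `ci` (95%), `p_t`,
#'   `p_wilcoxon`.
#' @export
paired_region_tests <- function(values_m, values_f) {
  if (length(values_m) != length(values_f) || length(values_m) < 2L) {
    stop_invalid("need two equal-length vectors of length >= 2")
  }
  d <- values_m - values_f
  if (all(d == 0)) stop_invalid("degenerate input: all paired differences are zero")
  tt <- stats::t.test(values_m, values_f, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(values_m, values_f, paired = TRUE,
                                            exact = length(d) <= 25L,
                                            correct = TRUE))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       mean_diff = unname(tt$estimate), ci = unname(tt$conf.int),
       p_t = tt$p.value, p_wilcoxon = wt$p.value)
}

#' Phenotypic sex difference from a linear model
#'
#' Fits `pheno ~ sex + age + age^2 + covariates` by OLS with sex coded
#' 0 = female, 1 = male, and returns the t statistic of the sex coefficient:
#' positive values mean higher in males.
#'
#' @param pheno raw trait vector.
#' @param sex vector coded 1 = male / 2 = female (or 0/1 with 1 = male, or a
#'   logical male indicator).
#' @param age numeric age vector; its square is added automatically.
#' @param covariates optional numeric matrix of further covariates.
#' @return list with `b` (sex coefficient), `se`, `t`, `p`, `df`, and the
#'   full `coefficients` table.
#' @export
phenotypic_sexdiff <- function(pheno, sex, age, covariates = NULL) {
  male <- sex_indicator(sex)
  X <- cbind(sex = male, age = age, age2 = age^2,
             if (is.null(covariates)) NULL else as.matrix(covariates))
  fit <- ols_fit(as.numeric(pheno), X)
  i <- match("sex", rownames(fit$coefficients))
  list(b = fit$coefficients[i, "estimate"], se = fit$coefficients[i, "se"],
       t = fit$coefficients[i, "t"], p = fit$coefficients[i, "p"],
       df = fit$df, coefficients = fit$coefficients)
}

sex_indicator <- function(sex) {
  if (is.logical(sex)) return(as.numeric(sex))
  sex <- as.integer(sex)
  if (all(sex %in% c(1L, 2L)) && any(sex == 2L)) return(as.numeric(sex == 1L))
  if (all(sex %in% c(0L, 1L))) return(as.numeric(sex))
  stop_invalid("'sex' must be coded 1/2 (male/female), 0/1 (1 = male), or logical")
}

# Small OLS helper with named coefficient table and rank checking.
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  Xd <- cbind("(intercept)" = 1, X)
  q <- qr(Xd)
  if (q$rank < ncol(Xd)) {
    bad <- colnames(Xd)[q$pivot[(q$rank + 1):ncol(Xd)]]
    stop_invalid("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(q, y)
  res <- qr.resid(q, y)
  df <- length(y) - ncol(Xd)
  if (df < 1L) stop_invalid("not enough observations for the design")
  s2 <- sum(res^2) / df
  xtxi <- chol2inv(qr.R(q))
  se <- sqrt(s2 * diag(xtxi))
  tv <- coefs / se
  tab <- cbind(estimate = coefs, se = se, t = tv,
               p = 2 * stats::pt(-abs(tv), df))
  list(coefficients = tab, df = df, sigma2 = s2, residuals = res)
}

#' Sex-specific scaling of genetic variance with phenotypic variance
#'
#' Across regions, fits the quadratic interaction model
#' `V_G = a + b V_P + c sex + d sex:V_P + e V_P^2 + f sex:V_P^2` (Model 1)
#' and, when the quadratic interaction `f` is not significant at
#' `alpha`, refits the nested linear interaction model
#' `V_G = a + b V_P + c sex + d sex:V_P` (Model 2) and reports `d` from it.
#' Sex is coded 0 = female, 1 = male, so `d` is the male-minus-female slope
#' contrast.
#'
#' @param table data.frame with columns `V_G`, `V_P` and `sex` (one row per
#'   region per sex; >= 2 regions per sex).
#' @param alpha significance level for dropping the quadratic terms.
#' @return An object of class `vgvp_fit`: `chosen` (`"Model 1"` or
#'   `"Model 2"`), per-model coefficient tables, and `d`/`f` rows with
#'   estimate, SE and p.
#' @export
fit_vg_vp_models <- function(table, alpha = 0.05) {
  need <- c("V_G", "V_P", "sex")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop_invalid("'table' needs columns %s", paste(need, collapse = ", "))
  }
  male <- sex_indicator(table$sex)
  if (min(sum(male == 1), sum(male == 0)) < 2L) {
    stop_invalid("need >= 2 regions per sex")
  }
  vp <- table$V_P
  X1 <- cbind(V_P = vp, sex = male, "sex:V_P" = male * vp,
              "V_P^2" = vp^2, "sex:V_P^2" = male * vp^2)
  m1 <- ols_fit(table$V_G, X1)
  f_row <- m1$coefficients["sex:V_P^2", ]
  X2 <- X1[, 1:3, drop = FALSE]
  m2 <- ols_fit(table$V_G, X2)
  use_m1 <- is.finite(f_row[["p"]]) && f_row[["p"]] < alpha
  chosen <- if (use_m1) "Model 1" else "Model 2"
  d_row <- (if (use_m1) m1 else m2)$coefficients["sex:V_P", ]
  structure(list(chosen = chosen,
                 d = d_row, f = f_row,
                 model1 = m1$coefficients, model2 = m2$coefficients,
                 rss1 = sum(m1$residuals^2), rss2 = sum(m2$residuals^2)),
            class = "vgvp_fit")
}

#' Pearson correlation between two regional maps
#'
#' @param map_a,map_b equal-length numeric vectors (length >= 3).
#' @return list with `r` and two-sided t-based `p`.
#' @export
correlate_maps <- function(map_a, map_b) {
  if (length(map_a) != length(map_b) || length(map_a) < 3L) {
    stop_invalid("need two equal-length maps of length >= 3")
  }
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop_invalid("zero variance in one of the maps")
  }
  ct <- stats::cor.test(map_a, map_b)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Screen sex-stratified GWAS records for sex-differentiated SNP effects
#'
#' Joins the two summary tables on variant id, harmonizes effect alleles
#' (records whose a1/a2 are swapped between sexes have one beta sign
#' flipped; variants with irreconcilable alleles, present in only one sex,
#' or untestable in either sex are excluded and counted), applies the Eq.-1
#' z test per variant, and assigns significance tiers against the relaxed
#' genome-wide threshold and the strict phenotype-corrected threshold.
#'
#' @param records_m,records_f data.frames from [run_stratified_gwas()] (or
#'   any table with columns `ID`, `A1`, `A2`, `BETA`, `SE`).
#' @param strict_n_tests phenotype count for the strict Bonferroni division
#'   (361 for the cortical panel: 360 regions + the global measure).
#' @param relaxed_alpha genome-wide base level (default 5e-8).
#' @return data.frame with columns `ID`, `BETA_M`, `SE_M`, `BETA_F`, `SE_F`,
#'   `Z`, `P`, `TIER` (`"none"`, `"relaxed"`, `"strict"`); excluded-variant
#'   counts are attached as attribute `excluded`.
#' @export
screen_snp_sexdiff <- function(records_m, records_f, strict_n_tests = 361L,
                               relaxed_alpha = 5e-8) {
  excl <- c(unmatched = 0L, allele_mismatch = 0L, untestable = 0L)
  common <- intersect(records_m$ID, records_f$ID)
  excl[["unmatched"]] <- (nrow(records_m) - length(common)) +
    (nrow(records_f) - length(common))
  m <- records_m[match(common, records_m$ID), ]
  f <- records_f[match(common, records_f$ID), ]
  same <- m$A1 == f$A1 & m$A2 == f$A2
  flipped <- m$A1 == f$A2 & m$A2 == f$A1
  bad <- !(same | flipped)
  excl[["allele_mismatch"]] <- sum(bad)
  beta_f <- ifelse(flipped, -f$BETA, f$BETA)
  usable <- !bad & is.finite(m$BETA) & is.finite(beta_f) &
    is.finite(m$SE) & is.finite(f$SE) & m$SE > 0 & f$SE > 0
  if ("STATUS" %in% names(m)) usable <- usable & m$STATUS == "ok"
  if ("STATUS" %in% names(f)) usable <- usable & f$STATUS == "ok"
  excl[["untestable"]] <- sum(!usable & !bad)
  m <- m[usable, ]
  f <- f[usable, ]
  beta_f <- beta_f[usable]
  zp <- zdiff(m$BETA, beta_f, m$SE, f$SE)
  strict <- mtc_threshold(relaxed_alpha, strict_n_tests)
  tier <- ifelse(zp$p < strict, "strict",
                 ifelse(zp$p < relaxed_alpha, "relaxed", "none"))
  out <- data.frame(ID = m$ID, BETA_M = m$BETA, SE_M = m$SE,
                    BETA_F = beta_f, SE_F = f$SE, Z = zp$z, P = zp$p,
                    TIER = tier, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  out
}
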