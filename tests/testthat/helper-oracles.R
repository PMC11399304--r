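# Independent oracles used across test files.  These deliberately avoid the
# package's own computational paths: the REML grid oracle works through an
# explicit eigendecomposition of V, the GWAS oracle through lm().

# Restricted log-likelihood -(log|V| + log|X'V^-1X| + y'Py)/2 for
# V = vg * A + ve * I, evaluated via the eigendecomposition of A.
oracle_loglik_grid <- function(y, A, vg_grid, ve_grid, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  yt <- drop(crossprod(e$vectors, y))
  Xt <- crossprod(e$vectors, X)
  grid <- expand.grid(vg = vg_grid, ve = ve_grid)
  grid$logL <- vapply(seq_len(nrow(grid)), function(i) {
    d <- grid$vg[i] * e$values + grid$ve[i]
    if (any(d <= 1e-12)) return(-Inf)
    XtViX <- crossprod(Xt, Xt / d)
    XtViy <- crossprod(Xt, yt / d)
    R <- tryCatch(chol(XtViX), error = function(err) NULL)
    if (is.null(R)) return(-Inf)
    sol <- backsolve(R, backsolve(R, XtViy, transpose = TRUE))
    yPy <- sum(yt^2 / d) - sum(XtViy * sol)
    -0.5 * (sum(log(d)) + 2 * sum(log(diag(R))) + yPy)
  }, 0)
  grid
}

# Two-stage (coarse then fine) grid maximizer of the restricted likelihood.
oracle_reml_grid <- function(y, A, coarse = 0.01, fine = 1e-3,
                             upper = NULL, X = NULL) {
  if (is.null(upper)) upper <- 2 * stats::var(y)
  g1 <- oracle_loglik_grid(y, A, seq(1e-6, upper, by = coarse),
                           seq(1e-6, upper, by = coarse), X = X)
  best <- g1[which.max(g1$logL), ]
  vg_rng <- seq(max(1e-6, best$vg - 2 * coarse), best$vg + 2 * coarse, by = fine)
  ve_rng <- seq(max(1e-6, best$ve - 2 * coarse), best$ve + 2 * coarse, by = fine)
  g2 <- oracle_loglik_grid(y, A, vg_rng, ve_rng, X = X)
  g2[which.max(g2$logL), ]
}

# Per-variant OLS through lm(), the normal-equations oracle for GWAS.
oracle_gwas_lm <- function(y, dosage, covariates = NULL) {
  m <- ncol(dosage)
  out <- data.frame(beta = numeric(m), se = numeric(m), t = numeric(m),
                    p = numeric(m))
  for (j in seq_len(m)) {
    dat <- data.frame(y = y, x = dosage[, j])
    if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
    fit <- summary(stats::lm(y ~ ., data = dat))
    out[j, ] <- fit$coefficients["x", ]
  }
  out
}

# Quick simulated trait over a panel: convenience wrapper for tests.
quick_sim <- function(n_male, n_female, m, h2 = 0.4, rg = 1, seed = 1,
                      n_causal = max(10L, m %/% 5L), m_x = 0L, ...) {
  cfg <- sim_config(n_male, n_female, m, m_x = m_x, seed = seed, ...)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, arch_spec(h2, h2, rg = rg,
                                              n_causal = n_causal),
                             seed = seed + 1000L)
  list(panel = panel, pheno = sim$phenotypes, truth = sim$truth)
}

# Split a simulated phenotype into the named per-sex vectors fit_bivariate
# expects.
split_by_sex <- function(pheno) {
  list(male = stats::setNames(pheno$y[pheno$sex == 1], pheno$iid[pheno$sex == 1]),
       female = stats::setNames(pheno$y[pheno$sex == 2], pheno$iid[pheno$sex == 2]))
}
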