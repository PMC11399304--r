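test_that("AI-REML matches the exhaustive grid oracle on small instances", {
  for (seed in 1:3) {
    sim <- quick_sim(25, 25, 120, h2 = 0.5, seed = seed * 10)
    g <- autosomal_grm(sim$panel)
    fit <- fit_reml(sim$pheno$y, grms = g, tol = 1e-8)
    grid <- oracle_reml_grid(sim$pheno$y, g$grm)
    # estimates within one fine grid step of the grid argmax
    expect_lt(abs(unname(fit$components[1]) - grid$vg), 1e-3 + 1e-9)
    expect_lt(abs(unname(fit$components[2]) - grid$ve), 1e-3 + 1e-9)
    # returned optimum at least as good as the grid's best
    expect_gte(fit$logL, grid$logL - 1e-4)
  }
})

test_that("direct and eigen restricted likelihoods agree", {
  sim <- quick_sim(30, 30, 100, h2 = 0.4, seed = 5)
  g <- autosomal_grm(sim$panel)
  fit <- fit_reml(sim$pheno$y, grms = g)
  th <- unname(fit$components)
  l_direct <- restricted_loglik(sim$pheno$y, grms = g, components = th,
                                method = "direct")
  l_eigen <- restricted_loglik(sim$pheno$y, grms = g, components = th,
                               method = "eigen")
  expect_equal(l_direct, l_eigen, tolerance = 1e-6)
  # and both agree with the logL the AI iterations report
  expect_equal(fit$logL, l_direct, tolerance = 1e-6)
})

test_that("null traits land at the variance boundary", {
  hits <- 0L
  n_rep <- 8L
  for (r in seq_len(n_rep)) {
    sim <- quick_sim(200, 200, 400, h2 = 0, seed = 300 + r)
    g <- autosomal_grm(sim$panel)
    fit <- fit_reml(sim$pheno$y, grms = g)
    if (fit$h2[["total"]] < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})

test_that("fixed effects are absorbed inside REML", {
  sim <- quick_sim(150, 150, 300, h2 = 0.5, seed = 21)
  covar <- cbind(pc1 = rnorm(300, sd = 1))
  y <- sim$pheno$y + 2 * covar[, 1]
  g <- autosomal_grm(sim$panel)
  fit <- fit_reml(y, covariates = covar, grms = g)
  fit0 <- fit_reml(sim$pheno$y, covariates = covar, grms = g)
  expect_equal(fit$components, fit0$components, tolerance = 1e-4)
  expect_error(fit_reml(y, covariates = cbind(covar, covar), grms = g),
               "singular")
})

test_that("h2 summaries use the delta method on the component covariance", {
  # V_G = V_E = 1 with unit, uncorrelated sampling variances:
  # h2 = 0.5, SE = sqrt((0.5/2)^2 * (1 + 1)) = 0.3536
  hs <- sexstratgen:::h2_from_components(c(`V(G)` = 1, `V(e)` = 1), diag(2), 1L)
  expect_equal(unname(hs$h2), c(0.5, 0.5))
  expect_equal(unname(hs$se[1]), sqrt(0.125), tolerance = 1e-12)
  # V_G = 0 => h2 = 0
  hs0 <- sexstratgen:::h2_from_components(c(0, 1), diag(2), 1L)
  expect_equal(unname(hs0$h2[1]), 0)
  # normalization: per-component h2 + V_E/V_P = 1
  sim <- quick_sim(100, 100, 200, h2 = 0.4, seed = 31)
  g <- autosomal_grm(sim$panel)
  fit <- fit_reml(sim$pheno$y, grms = g)
  expect_equal(sum(fit$h2[-length(fit$h2)]) +
                 fit$components[["V(e)"]] / fit$Vp, 1, tolerance = 1e-10)
  tab <- h2_summary(fit)
  expect_equal(tab$h2[nrow(tab)], fit$h2[["total"]])
})

test_that("lrt applies the boundary mixture convention", {
  expect_equal(lrt(-10, -10, mixture = TRUE)$p, 1)
  expect_equal(lrt(-10, -10, mixture = FALSE)$p, 1)
  r <- lrt(-8, -10, mixture = TRUE)     # delta logL = 2 -> stat 4
  expect_equal(r$statistic, 4)
  expect_equal(r$p, 0.5 * pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p, 0.02275, tolerance = 1e-3)
  # worse full model clamps to zero
  expect_equal(lrt(-12, -10)$statistic, 0)
})

test_that("mixture LRT is calibrated under the null h2 = 0", {
  n_rep <- 400L
  n <- 150L
  rej <- 0L
  for (r in seq_len(n_rep)) {
    sim <- quick_sim(n %/% 2, n %/% 2, 300, h2 = 0, seed = 5000 + r,
                     n_causal = 50L)
    g <- autosomal_grm(sim$panel)
    fit <- fit_reml(sim$pheno$y, grms = g)
    # profile the residual variance under the null (single parameter)
    opt <- optimize(function(ve) restricted_loglik(sim$pheno$y, grms = g,
                                                   components = c(0, ve),
                                                   method = "eigen"),
                    interval = c(1e-4, 4 * var(sim$pheno$y)), maximum = TRUE)
    p <- lrt(fit$logL, opt$objective, mixture = TRUE)$p
    if (p < 0.05) rej <- rej + 1L
  }
  band <- 2 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej / n_rep - 0.05), band + 0.01)
})

test_that("bivariate fit satisfies its identities and invariances", {
  sim <- quick_sim(120, 120, 250, h2 = 0.5, rg = 0.6, seed = 41,
                   n_causal = 100L)
  g <- autosomal_grm(sim$panel)
  ys <- split_by_sex(sim$pheno)
  fit <- fit_bivariate(ys$male, ys$female, grm = g)
  # r_g identity holds exactly for the returned fields
  expect_equal(fit$rg, fit$components[["C_G"]] /
                 sqrt(fit$components[["V_Gm"]] * fit$components[["V_Gf"]]),
               tolerance = 1e-12)
  expect_equal(fit$n_male, 120L)
  # permuting the sample order leaves all estimates unchanged
  perm <- sample(seq_len(n_samples(sim$panel)))
  panel2 <- subset_panel(sim$panel, samples = perm)
  g2 <- autosomal_grm(panel2)
  fit2 <- fit_bivariate(ys$male, ys$female, grm = g2)
  expect_equal(fit2$components, fit$components, tolerance = 1e-4)
  expect_equal(fit2$logL, fit$logL, tolerance = 1e-4)
  # local optimality: no perturbation improves the restricted likelihood
  V_at <- function(th) {
    A <- g$grm
    mvec <- as.numeric(g$ids$iid %in% names(ys$male))
    fvec <- 1 - mvec
    th[1] * A * tcrossprod(mvec) + th[2] * A * tcrossprod(fvec) +
      th[3] * A * (tcrossprod(mvec, fvec) + tcrossprod(fvec, mvec)) +
      diag(th[4] * mvec + th[5] * fvec)
  }
  X <- cbind(as.numeric(g$ids$iid %in% names(ys$male)),
             as.numeric(g$ids$iid %in% names(ys$female)))
  y <- ifelse(X[, 1] == 1, ys$male[g$ids$iid], ys$female[g$ids$iid])
  ll_at <- function(th) sexstratgen:::loglik_V(V_at(th), X, y)
  ll_hat <- ll_at(unname(fit$components))
  set.seed(42)
  for (i in 1:40) {
    th <- unname(fit$components) * exp(rnorm(5, sd = 0.08))
    expect_lte(ll_at(th), ll_hat + 1e-6)
  }
  # constrained refit satisfies |rg| = 1 by construction and never beats
  # the unconstrained optimum
  expect_lte(fit$logL_rg1, fit$logL + 1e-6)
})

test_that("bivariate recovery brackets the generating rg", {
  ok_1 <- 0L
  for (r in 1:3) {
    sim <- quick_sim(400, 400, 600, h2 = 0.5, rg = 1, seed = 600 + r,
                     n_causal = 300L)
    g <- autosomal_grm(sim$panel)
    ys <- split_by_sex(sim$pheno)
    fit <- fit_bivariate(ys$male, ys$female, grm = g)
    if (abs(fit$rg - 1) <= 2 * fit$rg_se) ok_1 <- ok_1 + 1L
  }
  expect_gte(ok_1, 2L)
  ok_5 <- 0L
  for (r in 1:3) {
    sim <- quick_sim(400, 400, 600, h2 = 0.5, rg = 0.5, seed = 700 + r,
                     n_causal = 300L)
    g <- autosomal_grm(sim$panel)
    ys <- split_by_sex(sim$pheno)
    fit <- fit_bivariate(ys$male, ys$female, grm = g)
    if (abs(fit$rg - 0.5) <= 2 * fit$rg_se) ok_5 <- ok_5 + 1L
  }
  expect_gte(ok_5, 2L)
})

test_that("hsq output contains the GCTA-style rows", {
  sim <- quick_sim(80, 80, 150, h2 = 0.4, seed = 51)
  g <- autosomal_grm(sim$panel)
  fit <- fit_reml(sim$pheno$y, grms = g)
  f <- tempfile(fileext = ".hsq")
  write_hsq(fit, f, logL_null = fit$logL - 3)
  lines <- readLines(f)
  expect_true(any(grepl("^Sum of V\\(G\\)/Vp", lines)))
  expect_true(any(grepl("^LRT", lines)))
  expect_true(any(grepl("^n\t", lines)))
})
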