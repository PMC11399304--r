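test_that("simulate_genotypes obeys its construction contract", {
  # all-female, fixed frequency, no missingness
  cfg <- sim_config(n_male = 0, n_female = 10, m_auto = 5,
                    maf_low = 0.5, maf_high = 0.5, missing_rate = 0, seed = 1)
  p <- simulate_genotypes(cfg)
  expect_equal(dim(p$dosage), c(10L, 5L))
  expect_true(all(p$dosage %in% 0:2))
  expect_true(all(p$fam$sex == 2L))
  expect_false(anyNA(p$dosage))

  # male X dosages are Binomial(1, p): binomial sampling oracle
  cfg <- sim_config(1000, 0, m_auto = 0, m_x = 100,
                    maf_low = 0.3, maf_high = 0.3, seed = 7)
  p <- simulate_genotypes(cfg)
  expect_true(all(p$dosage %in% 0:1))
  tol <- 3 * sqrt(0.3 * 0.7 / 1000)
  expect_true(all(abs(colMeans(p$dosage) - 0.3) < tol))

  # missingness masked at the configured rate: binomial oracle
  cfg <- sim_config(500, 500, m_auto = 1000, missing_rate = 0.1, seed = 3)
  p <- simulate_genotypes(cfg)
  expect_lt(abs(mean(is.na(p$dosage)) - 0.1), 3 * sqrt(0.1 * 0.9 / 1e6))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(0, 1, 5), "n_male \\+ n_female")
  expect_error(sim_config(5, 5, 0, 0), "at least one variant")
  expect_error(sim_config(5, 5, 5, maf_low = 0.4, maf_high = 0.1), "maf_low")
  expect_error(sim_config(5, 5, 5, missing_rate = 1), "missing_rate")
})

test_that("identical configs give byte-identical panels and phenotypes", {
  cfg <- sim_config(50, 50, 200, m_x = 20, missing_rate = 0.05, seed = 42)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1, p2)
  arch <- arch_spec(0.3, 0.5, rg = 0.8, n_causal = 50, mean_sex_gap = 0.2,
                    covariate_effects = c(age = 0.1))
  s1 <- simulate_phenotypes(p1, arch, seed = 9)
  s2 <- simulate_phenotypes(p2, arch, seed = 9)
  expect_identical(s1, s2)
})

test_that("simulate_phenotypes hits its architecture targets", {
  cfg <- sim_config(300, 300, 400, seed = 11)
  panel <- simulate_genotypes(cfg)

  # h2 = 0: genetic values identically zero
  s0 <- simulate_phenotypes(panel, arch_spec(0, 0, rg = 1, n_causal = 100),
                            seed = 1)
  expect_true(all(s0$truth$genetic_value == 0))

  # rg = 1: effect pairs exactly proportional
  s1 <- simulate_phenotypes(panel, arch_spec(0.4, 0.4, rg = 1, n_causal = 100),
                            seed = 2)
  expect_equal(cor(s1$truth$raw_beta_m, s1$truth$raw_beta_f), 1)

  # rg sweep {0, 0.5}: sample effect correlation brackets the target
  # (bivariate-normal sampling oracle)
  for (rg in c(0, 0.5)) {
    s5 <- simulate_phenotypes(panel, arch_spec(0.4, 0.4, rg = rg,
                                               n_causal = 400),
                              seed = 3)
    r <- cor(s5$truth$raw_beta_m, s5$truth$raw_beta_f)
    expect_lt(abs(r - rg), 2 * (1 - rg^2) / sqrt(400) + 0.02)
  }

  # mean sex gap and covariate slopes present
  arch <- arch_spec(0, 0, rg = 1, n_causal = 10, mean_sex_gap = 2,
                    covariate_effects = c(site = 1.5))
  sg <- simulate_phenotypes(panel, arch, seed = 4)
  ph <- sg$phenotypes
  gap <- mean(ph$y[ph$sex == 1] - 1.5 * ph$site[ph$sex == 1]) -
    mean(ph$y[ph$sex == 2] - 1.5 * ph$site[ph$sex == 2])
  expect_lt(abs(gap - 2), 0.25)
  expect_gt(cor(ph$y, ph$site), 0.5)
})

test_that("achieved heritability is within 0.02 of target at n >= 2000", {
  cfg <- sim_config(2000, 2000, 800, seed = 21)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, arch_spec(0.4, 0.6, rg = 1, n_causal = 200),
                             seed = 22)
  ph <- sim$phenotypes
  for (s in 1:2) {
    idx <- ph$sex == s
    frac <- var(sim$truth$genetic_value[idx]) / var(ph$y[idx])
    target <- if (s == 1) 0.4 else 0.6
    expect_lt(abs(frac - target), 0.02)
  }
})

test_that("recorded truth recomputes the genetic values exactly", {
  cfg <- sim_config(80, 80, 150, m_x = 30, seed = 31)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, arch_spec(0.5, 0.5, rg = 0.7, n_causal = 60),
                             seed = 32)
  tr <- sim$truth
  z <- sexstratgen:::scale_genotypes(panel, tr$dc_model)[, tr$causal]
  male <- panel$fam$sex == 1L
  g <- numeric(nrow(z))
  g[male] <- z[male, ] %*% tr$beta_m
  g[!male] <- z[!male, ] %*% tr$beta_f
  expect_equal(g, tr$genetic_value, tolerance = 1e-12)
})

test_that("inject_sexdiff_snp perturbs exactly the chosen sex x variant", {
  cfg <- sim_config(100, 100, 50, seed = 41)
  panel <- simulate_genotypes(cfg)
  zero <- data.frame(fid = panel$fam$fid, iid = panel$fam$iid,
                     sex = panel$fam$sex, y = 0)
  # zero effects: unchanged
  r0 <- inject_sexdiff_snp(panel, zero, 5, 0, 0)
  expect_equal(r0$phenotypes$y, zero$y)
  # male-only effect on zero background: male phenotype == dosage column
  r1 <- inject_sexdiff_snp(panel, zero, 5, 1, 0)
  male <- panel$fam$sex == 1L
  expect_equal(r1$phenotypes$y[male], unname(panel$dosage[male, 5]))
  expect_true(all(r1$phenotypes$y[!male] == 0))
  # monomorphic in one sex: warning
  panel2 <- panel
  panel2$dosage[male, 7] <- 0
  expect_warning(inject_sexdiff_snp(panel2, zero, 7, 1, 1), "monomorphic")
  # out-of-range / non-finite input
  expect_error(inject_sexdiff_snp(panel, zero, 1000, 1, 0), "out of range")
  expect_error(inject_sexdiff_snp(panel, zero, 5, Inf, 0), "finite")
})

test_that("an injected effect is detectable downstream of the z screen", {
  set.seed(51)
  cfg <- sim_config(2000, 2000, 200, maf_low = 0.3, maf_high = 0.3, seed = 52)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, arch_spec(0, 0, rg = 1, n_causal = 10),
                             seed = 53)
  inj <- inject_sexdiff_snp(panel, sim$phenotypes, 17, 0.3, 0)
  y <- inj$phenotypes$y
  gm <- run_stratified_gwas(panel, y, sex_group = "male")
  gf <- run_stratified_gwas(panel, y, sex_group = "female")
  scr <- screen_snp_sexdiff(gm, gf)
  expect_equal(scr$ID[which.min(scr$P)], "snp17")
})

test_that("simulate_region_panel builds a labeled spherical parcellation", {
  cfg <- sim_config(100, 100, 300, seed = 61)
  panel <- simulate_genotypes(cfg)
  rp <- simulate_region_panel(panel, n_regions = 30, n_networks = 5,
                              h2_profile = 0.3, seed = 62)
  a <- rp$annotations
  expect_s3_class(a, "region_annotation")
  expect_equal(nrow(a), 30L)
  # unit-norm centroids
  expect_true(all(abs(sqrt(a$x^2 + a$y^2 + a$z^2) - 1) < 1e-9))
  # labels partition the regions
  expect_equal(sum(table(a$network)), 30L)
  expect_true(all(a$network %in% 1:5))
  expect_length(rp$phenotypes, 30L)
  expect_error(simulate_region_panel(panel, 3, 5, 0.3), "n_regions >= n_networks")
})

test_that("regional REML recovers a constant h2 profile on average", {
  cfg <- sim_config(250, 250, 1000, seed = 71)
  panel <- simulate_genotypes(cfg)
  g <- autosomal_grm(panel)
  rp <- simulate_region_panel(panel, n_regions = 20, n_networks = 4,
                              h2_profile = 0.3, seed = 72, n_causal = 200)
  h2 <- vapply(rp$phenotypes, function(ph) {
    fit_reml(ph$y, grms = g)$h2[["total"]]
  }, 0)
  se_mean <- sd(h2) / sqrt(length(h2))
  expect_lt(abs(mean(h2) - 0.3), 2 * se_mean + 0.02)
})

test_that("truth sidecar writes valid JSON", {
  cfg <- sim_config(20, 20, 30, seed = 81)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, arch_spec(0.2, 0.2, rg = 1, n_causal = 5),
                             seed = 82)
  f <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$causal, sim$truth$causal)
  expect_equal(back$h2_male, 0.2)
})
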