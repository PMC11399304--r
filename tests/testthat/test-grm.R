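toy_panel <- function(dosage, sex, chrom = NULL) {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(1L, m)
  genotype_panel(dosage, sex = sex,
                 map = data.frame(chrom = chrom, id = paste0("v", seq_len(m)),
                                  pos = seq_len(m), a1 = "A", a2 = "C",
                                  stringsAsFactors = FALSE))
}

test_that("autosomal GRM matches the hand-worked 3x2 example", {
  panel <- toy_panel(rbind(c(0, 2), c(1, 1), c(2, 0)), sex = c(1, 1, 2))
  g <- autosomal_grm(panel)
  # p = 0.5 for both variants; standardized dosages (x - 1)/sqrt(0.5)
  expect_equal(unname(g$grm),
               rbind(c(2, 0, -2), c(0, 0, 0), c(-2, 0, 2)),
               tolerance = 1e-12)
  expect_true(all(g$n_pairs == 2))
})

test_that("GRM structural invariants hold", {
  cfg <- sim_config(60, 60, 200, seed = 1)
  panel <- simulate_genotypes(cfg)
  g <- autosomal_grm(panel)
  expect_identical(g$grm, t(g$grm))
  expect_true(all(is.finite(g$grm)))

  # duplicated sample: off-diagonal equals the diagonal
  d2 <- panel$dosage[c(1, 1, 2:20), ]
  p2 <- toy_panel(d2, sex = panel$fam$sex[c(1, 1, 2:20)])
  g2 <- autosomal_grm(p2)
  expect_equal(g2$grm[1, 2], g2$grm[1, 1], tolerance = 1e-12)

  # appending a monomorphic variant changes nothing
  p3 <- toy_panel(cbind(panel$dosage, mono = rep(2, 120)),
                  sex = panel$fam$sex)
  g3 <- autosomal_grm(p3)
  expect_equal(g3$grm, g$grm, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("GRM on HWE-unrelated panels is calibrated", {
  cfg <- sim_config(250, 250, 2000, seed = 2)
  panel <- simulate_genotypes(cfg)
  g <- autosomal_grm(panel)
  expect_lt(abs(mean(diag(g$grm)) - 1), 0.05)
  off <- g$grm[upper.tri(g$grm)]
  expect_lt(abs(sd(off) - 1 / sqrt(2000)), 0.2 / sqrt(2000))
})

test_that("x_grm codes males per dosage-compensation model", {
  # 2 males, 1 X variant, raw values (0, 1): p = 0.5
  panel <- toy_panel(cbind(c(0, 1)), sex = c(1, 1), chrom = 23L)
  # FDC: (2x - 1)/sqrt(0.5) -> (-sqrt(2), sqrt(2))
  g <- x_grm(panel, dc_model = "FDC")
  expect_equal(unname(g$grm), rbind(c(2, -2), c(-2, 2)), tolerance = 1e-12)
  # NDC: (x - 0.5)/sqrt(0.5) -> (-1/sqrt(2), 1/sqrt(2))
  g <- x_grm(panel, dc_model = "NDC")
  expect_equal(unname(g$grm), rbind(c(0.5, -0.5), c(-0.5, 0.5)),
               tolerance = 1e-12)
  # EV: (x - 0.5)/sqrt(0.25) -> (-1, 1)
  g <- x_grm(panel, dc_model = "EV")
  expect_equal(unname(g$grm), rbind(c(1, -1), c(-1, 1)), tolerance = 1e-12)
})

test_that("x_grm is model-invariant on all-female panels and symmetric on mixed ones", {
  cfg <- sim_config(0, 80, 0, m_x = 100, seed = 3)
  panel <- simulate_genotypes(cfg)
  gf <- x_grm(panel, dc_model = "FDC")
  expect_equal(gf$grm, x_grm(panel, dc_model = "NDC")$grm, tolerance = 1e-12)
  expect_equal(gf$grm, x_grm(panel, dc_model = "EV")$grm, tolerance = 1e-12)

  cfg <- sim_config(40, 40, 0, m_x = 100, seed = 4)
  mixed <- simulate_genotypes(cfg)
  for (dc in c("FDC", "NDC", "EV")) {
    g <- x_grm(mixed, dc_model = dc)
    expect_identical(g$grm, t(g$grm))
  }
})

test_that("FDC equals the autosomal estimator on pre-doubled male dosages", {
  # all-male panel: the X allele frequency (one allele per male) equals the
  # autosomal frequency of the doubled dosages, so the equivalence is exact
  cfg <- sim_config(100, 0, 0, m_x = 50, seed = 5)
  panel <- simulate_genotypes(cfg)
  gx <- x_grm(panel, dc_model = "FDC")
  doubled <- toy_panel(2 * panel$dosage, sex = panel$fam$sex)
  ga <- autosomal_grm(doubled)
  expect_equal(gx$grm, ga$grm, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dc-model selection prefers the generating coding and breaks ties", {
  # exact tie table: priority FDC > EV > NDC
  tab <- data.frame(model = c("FDC", "NDC", "EV"), logL = c(-10, -10, -10),
                    converged = TRUE)
  expect_equal(sexstratgen:::pick_dc_model(tab), "FDC")
  tab$logL <- c(-20, -10, -10)
  expect_equal(sexstratgen:::pick_dc_model(tab), "EV")
  tab$converged <- c(TRUE, TRUE, FALSE)
  expect_equal(sexstratgen:::pick_dc_model(tab), "NDC")

  # simulation: X-linked signal generated under full dosage compensation.
  # Pooled scaling preserves the coding-implied male/female genetic-variance
  # ratio (2:1 under FDC) with homoscedastic noise — the world the combined-
  # sex dosage-compensation comparison assumes; causal variants X-only.
  wins <- 0L
  n_rep <- 6L
  for (r in seq_len(n_rep)) {
    cfg_x <- sim_config(300, 300, 0, m_x = 400, seed = 100 + r)
    panel_x <- simulate_genotypes(cfg_x)
    cfg_a <- sim_config(300, 300, 400, seed = 150 + r)
    panel_a <- simulate_genotypes(cfg_a)
    sim <- simulate_phenotypes(panel_x,
                               arch_spec(0.3, 0.3, rg = 1, n_causal = 300,
                                         dc_model = "FDC", scale = "pooled"),
                               seed = 200 + r)
    auto <- autosomal_grm(panel_a)       # same individuals, null autosomes
    xg <- lapply(c(FDC = "FDC", NDC = "NDC", EV = "EV"),
                 function(dc) x_grm(panel_x, dc_model = dc))
    sel <- select_dc_model(sim$phenotypes$y, auto_grm = auto, x_grms = xg)
    expect_equal(nrow(sel$table), 3L)
    if (sel$model == "FDC") wins <- wins + 1L
  }
  expect_gte(wins, n_rep / 2)
})

test_that("relatedness pruning removes a minimal deterministic set", {
  base <- diag(4)
  ids <- data.frame(fid = paste0("F", 1:4), iid = paste0("I", 1:4))
  mk <- function(mat) sexstratgen:::new_grm(mat, matrix(100, 4, 4), ids,
                                            "autosomal", "test")
  # no pair above threshold: all kept
  expect_equal(prune_relatedness(mk(base), 0.05), ids$iid)
  # one duplicated pair: exactly one removed (the later id)
  dup <- base; dup[1, 2] <- dup[2, 1] <- 0.9
  expect_equal(prune_relatedness(mk(dup), 0.05), c("I1", "I3", "I4"))
  # chain A-B, B-C above threshold, A-C below: only B removed (the
  # brute-force minimum vertex cover of the 3-node path)
  chain <- base
  chain[1, 2] <- chain[2, 1] <- 0.1
  chain[2, 3] <- chain[3, 2] <- 0.1
  expect_equal(prune_relatedness(mk(chain), 0.05), c("I1", "I3", "I4"))
})

test_that("GCTA binary GRM round-trips at float32 precision", {
  cfg <- sim_config(30, 30, 120, missing_rate = 0.05, seed = 6)
  panel <- simulate_genotypes(cfg)
  g <- autosomal_grm(panel)
  prefix <- tempfile()
  write_gcta_grm(g, prefix)
  back <- read_gcta_grm(prefix)
  expect_equal(back$ids$iid, g$ids$iid)
  expect_lt(max(abs(back$grm - g$grm)), 1e-6 * max(1, max(abs(g$grm))))
  expect_equal(back$n_pairs, g$n_pairs, tolerance = 1e-6, ignore_attr = TRUE)
  # layout check: first three stored floats are g11, g21, g22
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = 3, size = 4,
                  endian = "little")
  expect_equal(vals, c(g$grm[1, 1], g$grm[2, 1], g$grm[2, 2]),
               tolerance = 1e-6)
})

test_that("PLINK bed and dosage TSV round-trips preserve the panel", {
  cfg <- sim_config(25, 25, 40, m_x = 10, missing_rate = 0.1, seed = 7)
  panel <- simulate_genotypes(cfg)
  prefix <- tempfile()
  write_plink(panel, prefix)
  back <- read_plink(prefix)
  expect_equal(back$dosage, panel$dosage, ignore_attr = TRUE)
  expect_equal(back$fam$sex, panel$fam$sex)
  expect_equal(back$map$chrom, panel$map$chrom)

  f <- tempfile(fileext = ".tsv")
  write_dosage_tsv(panel, f)
  back2 <- read_dosage_tsv(f)
  expect_equal(back2$dosage, panel$dosage, ignore_attr = TRUE)
  expect_equal(back2$fam, panel$fam, ignore_attr = TRUE)
})

test_that("bed encoding matches the PLINK1 two-bit spec on a known fixture", {
  # 4 samples, 1 variant, dosages (2, 1, 0, NA):
  # codes 00, 10, 11, 01 packed little-endian-first => byte 01 11 10 00b
  panel <- toy_panel(cbind(c(2, 1, 0, NA)), sex = c(1, 2, 1, 2))
  prefix <- tempfile()
  write_plink(panel, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 4)
  expect_identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  expect_identical(raw[4], as.raw(0x0 + 2 * 4 + 3 * 16 + 1 * 64))
})
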