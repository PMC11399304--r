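#' Simulation configuration
#'
#' Describes a synthetic genotype panel: sample sizes per sex, autosomal and
#' X-chromosome variant counts, the allele-frequency band variants are drawn
#' from, and a missing-call rate.  Identical configurations (including the
#' seed) always produce byte-identical panels.
#'
#' @param n_male,n_female number of XY / XX individuals (`n_male + n_female
#'   >= 2`).
#' @param m_auto,m_x number of autosomal / X-chromosome variants (total >= 1).
#' @param maf_low,maf_high allele-frequency bounds in (0, 0.5]; per-variant
#'   frequencies are drawn uniformly from this interval (set both equal for a
#'   fixed frequency).
#' @param missing_rate completely-at-random missing-call proportion in [0, 1).
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_male, n_female, m_auto, m_x = 0L,
                       maf_low = 0.05, maf_high = 0.5,
                       missing_rate = 0, seed = 1L) {
  n_male <- check_count(n_male, "n_male")
  n_female <- check_count(n_female, "n_female")
  if (n_male + n_female < 2L) stop_invalid("need n_male + n_female >= 2")
  m_auto <- check_count(m_auto, "m_auto")
  m_x <- check_count(m_x, "m_x")
  if (m_auto + m_x < 1L) stop_invalid("need at least one variant")
  maf_low <- check_prob(maf_low, "maf_low", lo = 0, hi = 0.5, lo_open = TRUE)
  maf_high <- check_prob(maf_high, "maf_high", lo = 0, hi = 0.5, lo_open = TRUE)
  if (maf_low > maf_high) stop_invalid("maf_low must be <= maf_high")
  missing_rate <- check_prob(missing_rate, "missing_rate", hi = 1, hi_open = TRUE)
  structure(list(n_male = n_male, n_female = n_female, m_auto = m_auto,
                 m_x = m_x, maf_low = maf_low, maf_high = maf_high,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype panel under Hardy-Weinberg equilibrium
#'
#' Autosomal and female X dosages are Binomial(2, p) draws; male X values are
#' Binomial(1, p) (raw hemizygous coding).  Variants are independent (no
#' linkage disequilibrium).  Missing calls are masked completely at random.
#'
#' @param config a [sim_config()].
#' @return A [genotype_panel()].  Autosomes are assigned chromosomes 1..22
#'   round-robin; X variants get chromosome 23.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_male + config$n_female
    m <- config$m_auto + config$m_x
    sex <- rep(c(1L, 2L), c(config$n_male, config$n_female))
    p <- stats::runif(m, config$maf_low, config$maf_high)
    dosage <- matrix(NA_real_, n, m)
    if (config$m_auto > 0L) {
      ja <- seq_len(config$m_auto)
      dosage[, ja] <- stats::rbinom(n * config$m_auto, 2L,
                                    rep(p[ja], each = n))
    }
    if (config$m_x > 0L) {
      jx <- config$m_auto + seq_len(config$m_x)
      ploidy <- ifelse(sex == 1L, 1L, 2L)
      dosage[, jx] <- stats::rbinom(n * config$m_x,
                                    rep(ploidy, times = config$m_x),
                                    rep(p[jx], each = n))
    }
    if (config$missing_rate > 0) {
      dosage[stats::runif(n * m) < config$missing_rate] <- NA_real_
    }
    chrom <- c(if (config$m_auto > 0L)
                 rep_len(1:22, config$m_auto) else integer(0),
               rep(23L, config$m_x))
    map <- data.frame(chrom = chrom,
                      id = paste0("snp", seq_len(m)),
                      pos = seq_len(m) * 1000L,
                      a1 = "A", a2 = "C",
                      stringsAsFactors = FALSE)
    genotype_panel(dosage, sex = sex, map = map)
  })
}

#' Genetic-architecture specification
#'
#' Targets for the per-sex polygenic architecture of one simulated trait:
#' SNP-heritabilities, the between-sex correlation of causal effect sizes,
#' the number of causal variants, a mean sex gap, and fixed covariate
#' effects.
#'
#' @param h2_male,h2_female target SNP-heritabilities in [0, 1).
#' @param rg between-sex correlation of causal effects in [-1, 1].
#' @param n_causal number of causal variants (must not exceed the panel size
#'   when the spec is used).
#' @param mean_sex_gap constant added to male phenotypes (trait units).
#' @param covariate_effects named numeric vector of slopes; one standard
#'   normal covariate is generated per entry and added with that slope.
#' @param dc_model dosage-compensation coding assumed for male X causal
#'   variants when standardizing genotypes; one of `"FDC"`, `"NDC"`, `"EV"`.
#' @param scale `"per_sex"` (default): each sex's genetic value is rescaled
#'   so its sample variance hits that sex's h2 target exactly.  `"pooled"`:
#'   one common factor scales the pooled genetic value to the (shared) h2
#'   target, preserving any between-sex genetic-variance ratio implied by
#'   the X dosage-compensation coding — the world dosage-compensation model
#'   selection assumes; requires `h2_male == h2_female`.
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(h2_male, h2_female, rg = 1, n_causal,
                      mean_sex_gap = 0, covariate_effects = NULL,
                      dc_model = c("FDC", "NDC", "EV"),
                      scale = c("per_sex", "pooled")) {
  h2_male <- check_prob(h2_male, "h2_male", hi = 1, hi_open = TRUE)
  h2_female <- check_prob(h2_female, "h2_female", hi = 1, hi_open = TRUE)
  rg <- check_prob(rg, "rg", lo = -1, hi = 1)
  n_causal <- check_count(n_causal, "n_causal", min = 1L)
  if (!is.null(covariate_effects)) {
    if (is.list(covariate_effects)) covariate_effects <- unlist(covariate_effects)
    if (is.null(names(covariate_effects)) || any(names(covariate_effects) == "")) {
      stop_invalid("'covariate_effects' must be a named numeric vector")
    }
  }
  scale <- match.arg(scale)
  if (scale == "pooled" && h2_male != h2_female) {
    stop_invalid("'pooled' scaling requires equal h2 targets")
  }
  structure(list(h2_male = h2_male, h2_female = h2_female, rg = rg,
                 n_causal = n_causal, mean_sex_gap = as.numeric(mean_sex_gap),
                 covariate_effects = covariate_effects,
                 dc_model = match.arg(dc_model), scale = scale),
            class = "arch_spec")
}

# Column-standardized genotype matrix (mean 0, sample variance 1 per variant)
# with male X first coded per dc_model; missing entries contribute 0 after
# centering.  Monomorphic variants become all-zero columns.
scale_genotypes <- function(panel, dc_model = "FDC") {
  d <- panel$dosage
  xv <- is_x_chrom(panel$map$chrom)
  male <- panel$fam$sex == 1L
  if (any(xv) && any(male)) {
    w <- switch(dc_model, FDC = 2, NDC = 1, EV = sqrt(2),
                stop_invalid("unknown dc_model '%s'", dc_model))
    d[male, xv] <- d[male, xv] * w
  }
  mu <- colMeans(d, na.rm = TRUE)
  sdv <- apply(d, 2L, stats::sd, na.rm = TRUE)
  z <- sweep(d, 2L, mu, "-")
  z[is.na(z)] <- 0
  keep <- !is.na(sdv) & sdv > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2L, sdv[keep], "/")
  z[, !keep] <- 0
  z
}

#' Simulate sex-stratified polygenic phenotypes
#'
#' Causal effect pairs (beta_m, beta_f) are drawn from a zero-mean bivariate
#' normal with correlation `rg`, applied to column-standardized genotypes,
#' and the per-sex genetic values are rescaled so their realized sample
#' variance equals the heritability target exactly.  Residual noise is
#' independent N(0, 1 - h2); covariates and the mean sex gap are added on
#' top.  Everything needed to recompute the genetic values is returned as a
#' `simulation_truth` object.
#'
#' @param panel a [genotype_panel()].
#' @param arch an [arch_spec()].
#' @param seed integer RNG seed for effects, noise and covariates.
#' @return A list with `phenotypes` (data.frame: fid, iid, sex, y, one column
#'   per covariate) and `truth` (class `simulation_truth`).
#' @export
simulate_phenotypes <- function(panel, arch, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(arch, "arch_spec"))
  m <- n_variants(panel)
  n <- n_samples(panel)
  if (arch$n_causal > m) stop_invalid("n_causal (%d) exceeds panel variants (%d)",
                                      arch$n_causal, m)
  male <- panel$fam$sex == 1L
  if ((arch$h2_male != arch$h2_female || arch$rg < 1) &&
      (!any(male) || all(male))) {
    stop_invalid("panel must contain both sexes when h2 targets differ or rg < 1")
  }
  with_seed(seed, {
    causal <- sort(sample.int(m, arch$n_causal))
    # bivariate normal effect pairs with correlation rg
    u1 <- stats::rnorm(arch$n_causal)
    u2 <- stats::rnorm(arch$n_causal)
    beta_m <- u1
    beta_f <- arch$rg * u1 + sqrt(1 - arch$rg^2) * u2
    z <- scale_genotypes(panel, arch$dc_model)[, causal, drop = FALSE]
    g <- numeric(n)
    g[male] <- z[male, , drop = FALSE] %*% beta_m
    g[!male] <- z[!male, , drop = FALSE] %*% beta_f
    if (arch$scale == "pooled") {
      scale_m <- scale_f <- rescale_factor(g, arch$h2_male)
      g <- g * scale_m
    } else {
      scale_m <- scale_f <- 0
      if (any(male)) {
        scale_m <- rescale_factor(g[male], arch$h2_male)
        g[male] <- g[male] * scale_m
      }
      if (any(!male)) {
        scale_f <- rescale_factor(g[!male], arch$h2_female)
        g[!male] <- g[!male] * scale_f
      }
    }
    e <- numeric(n)
    e[male] <- stats::rnorm(sum(male), sd = sqrt(1 - arch$h2_male))
    e[!male] <- stats::rnorm(sum(!male), sd = sqrt(1 - arch$h2_female))
    y <- g + e
    y[male] <- y[male] + arch$mean_sex_gap
    pheno <- data.frame(fid = panel$fam$fid, iid = panel$fam$iid,
                        sex = panel$fam$sex, y = y,
                        stringsAsFactors = FALSE)
    if (!is.null(arch$covariate_effects)) {
      for (nm in names(arch$covariate_effects)) {
        v <- stats::rnorm(n)
        pheno[[nm]] <- v
        pheno$y <- pheno$y + arch$covariate_effects[[nm]] * v
      }
    }
    truth <- structure(list(causal = causal,
                            beta_m = beta_m * scale_m,
                            beta_f = beta_f * scale_f,
                            raw_beta_m = beta_m, raw_beta_f = beta_f,
                            h2_male = arch$h2_male, h2_female = arch$h2_female,
                            rg = arch$rg, dc_model = arch$dc_model,
                            genetic_value = g, injected = NULL,
                            seed = as.integer(seed)),
                       class = "simulation_truth")
    list(phenotypes = pheno, truth = truth)
  })
}

# Factor that maps a genetic-value vector to sample variance h2 exactly.
rescale_factor <- function(g, h2) {
  if (h2 == 0) return(0)
  s <- stats::sd(g)
  if (!is.finite(s) || s == 0) {
    stop_invalid("genetic value degenerate (no causal variation); cannot hit h2 target")
  }
  sqrt(h2) / s
}

#' Inject a sex-differentiated variant effect into a phenotype
#'
#' Adds `beta_m * dosage` to male phenotypes and `beta_f * dosage` to female
#' phenotypes for one chosen variant (raw dosages; missing calls contribute
#' 0).  Issues a warning when the variant is monomorphic in either sex, since
#' downstream sex-difference power there is nil.
#'
#' @param panel a [genotype_panel()].
#' @param pheno phenotype data.frame from [simulate_phenotypes()].
#' @param variant_index column index of the variant to perturb.
#' @param beta_m,beta_f finite per-sex allele effects.
#' @param truth optional `simulation_truth` to update.
#' @return A list with updated `phenotypes` and `truth`.
#' @export
inject_sexdiff_snp <- function(panel, pheno, variant_index, beta_m, beta_f,
                               truth = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  variant_index <- check_count(variant_index, "variant_index", min = 1L)
  if (variant_index > n_variants(panel)) stop_invalid("variant_index out of range")
  if (!is.finite(beta_m) || !is.finite(beta_f)) {
    stop_invalid("beta_m and beta_f must be finite")
  }
  x <- panel$dosage[, variant_index]
  x[is.na(x)] <- 0
  male <- pheno$sex == 1L
  for (s in c("male", "female")) {
    sel <- if (s == "male") male else !male
    if (sum(sel) > 0L && length(unique(x[sel])) < 2L) {
      warning(sprintf("variant %d is monomorphic in the %s group; no power to detect a sex-differentiated effect",
                      variant_index, s))
    }
  }
  pheno$y[male] <- pheno$y[male] + beta_m * x[male]
  pheno$y[!male] <- pheno$y[!male] + beta_f * x[!male]
  if (!is.null(truth)) {
    truth$injected <- rbind(truth$injected,
                            data.frame(variant = variant_index,
                                       beta_m = beta_m, beta_f = beta_f))
  }
  list(phenotypes = pheno, truth = truth)
}

# Deterministic Fibonacci lattice of k points on the unit sphere.
fibonacci_sphere <- function(k) {
  i <- seq_len(k) - 0.5
  z <- 1 - 2 * i / k
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Simulate a spherical multi-region phenotype panel
#'
#' Emulates a bilateral cortical parcellation: region centroids are placed on
#' the unit sphere by a deterministic Fibonacci lattice (mirrored across
#' hemispheres), network labels are assigned by nearest of `n_networks` seed
#' centroids (great-circle distance), and each region's phenotype is
#' simulated on `panel` with its own heritability from `h2_profile`.
#'
#' @param panel a [genotype_panel()] the regional phenotypes are simulated on.
#' @param n_regions total number of regions (split as evenly as possible
#'   between hemispheres); `n_regions >= n_networks >= 1`.
#' @param n_networks number of network labels.
#' @param h2_profile per-region heritability target(s); recycled to
#'   `n_regions`.
#' @param seed integer RNG seed.
#' @param n_causal causal variants per regional trait (default
#'   `min(100, n_variants(panel))`).
#' @param rg between-sex effect correlation shared by all regions.
#' @return A list with `phenotypes` (list of per-region phenotype
#'   data.frames), `annotations` (a [region_annotation()] data.frame), and
#'   `truths` (list of `simulation_truth`).
#' @export
simulate_region_panel <- function(panel, n_regions, n_networks, h2_profile,
                                  seed = 1L, n_causal = NULL, rg = 1) {
  n_regions <- check_count(n_regions, "n_regions", min = 1L)
  n_networks <- check_count(n_networks, "n_networks", min = 1L)
  if (n_regions < n_networks) stop_invalid("need n_regions >= n_networks")
  h2 <- rep_len(as.numeric(h2_profile), n_regions)
  if (is.null(n_causal)) n_causal <- min(100L, n_variants(panel))
  n_left <- ceiling(n_regions / 2)
  left <- fibonacci_sphere(n_left)
  right <- left[seq_len(n_regions - n_left), , drop = FALSE]
  right[, 1] <- -right[, 1]
  cent <- rbind(left, right)
  hemi <- rep(c("L", "R"), c(n_left, n_regions - n_left))
  seeds <- fibonacci_sphere(n_networks)
  # nearest seed by great-circle distance == max cosine similarity
  network <- max.col(cent %*% t(seeds), ties.method = "first")
  annot <- region_annotation(region = paste0("region", seq_len(n_regions)),
                             hemi = hemi, centroid = cent, network = network)
  phenos <- vector("list", n_regions)
  truths <- vector("list", n_regions)
  for (r in seq_len(n_regions)) {
    arch <- arch_spec(h2_male = h2[r], h2_female = h2[r], rg = rg,
                      n_causal = n_causal)
    sim <- simulate_phenotypes(panel, arch, seed = seed + r)
    phenos[[r]] <- sim$phenotypes
    truths[[r]] <- sim$truth
  }
  names(phenos) <- names(truths) <- annot$region
  list(phenotypes = phenos, annotations = annot, truths = truths)
}

#' Write / read a phenotype table TSV
#'
#' Columns: `fid`, `iid`, `sex`, the trait(s), and any covariates.
#'
#' @param pheno phenotype data.frame (e.g. from [simulate_phenotypes()]).
#' @param file path.
#' @export
write_phenotype_tsv <- function(pheno, file) {
  utils::write.table(pheno, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a simulation-truth sidecar as JSON
#'
#' @param truth a `simulation_truth`.
#' @param file output path.
#' @export
write_truth_json <- function(truth, file) {
  stopifnot(inherits(truth, "simulation_truth"))
  jsonlite::write_json(unclass(truth), file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}
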