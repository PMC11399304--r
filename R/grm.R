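#' Genetic relationship matrices
#'
#' GRMs follow the GCTA convention: the (j, k) entry is the average over
#' usable variants of the product of per-variant standardized dosages,
#' `(x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`, with `p_i` the allele
#' frequency estimated on the analysis subset.  Monomorphic variants are
#' excluded; missing genotypes are excluded pairwise, with the per-pair
#' usable-variant counts kept alongside the matrix (the GCTA `N` matrix).
#'
#' @name grm
NULL

new_grm <- function(mat, n_pairs, ids, source, freq_basis) {
  structure(list(grm = symmetrize(mat), n_pairs = n_pairs,
                 ids = ids, source = source, freq_basis = freq_basis),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$grm)
  off <- x$grm[upper.tri(x$grm)]
  cat(sprintf("grm (%s): %d samples; mean diagonal %.4f; off-diagonal sd %.4f\n",
              x$source, n, mean(diag(x$grm)), stats::sd(off)))
  invisible(x)
}

# Shared core: GRM from an already-standardized matrix z (NA -> 0) with an
# observation mask and a usable-variant flag.
grm_from_scaled <- function(z, obs, usable, ids, source, freq_basis) {
  z <- z[, usable, drop = FALSE]
  if (ncol(z) == 0L) stop_invalid("no polymorphic variants; GRM would be empty")
  mat_sum <- tcrossprod(z)
  if (all(obs)) {           # no missing calls: constant per-pair count
    n_pairs <- matrix(ncol(z), nrow(z), nrow(z))
    mat <- mat_sum / ncol(z)
  } else {
    obs <- obs[, usable, drop = FALSE]
    storage.mode(obs) <- "double"
    n_pairs <- tcrossprod(obs)
    if (any(n_pairs == 0)) {
      warning("some sample pairs share no usable variant; their GRM entries are NA")
    }
    mat <- mat_sum / n_pairs
    mat[n_pairs == 0] <- NA_real_
  }
  new_grm(mat, n_pairs, ids, source, freq_basis)
}

#' Autosomal GRM
#'
#' @param panel a [genotype_panel()].
#' @param sample_subset optional sample selector (indices, mask, or iids)
#'   defining the analysis subset; allele frequencies are estimated on it.
#' @return A `grm` object.
#' @examples
#' # 3 samples x 2 variants with dosages 0/1/2 and 2/1/0: both freqs 0.5
#' p <- genotype_panel(rbind(c(0, 2), c(1, 1), c(2, 0)), sex = c(1, 1, 2),
#'                     map = data.frame(chrom = 1:2, id = c("a", "b"),
#'                                      pos = 1:2, a1 = "A", a2 = "C"))
#' autosomal_grm(p)$grm   # [[2,0,-2],[0,0,0],[-2,0,2]]
#' @export
autosomal_grm <- function(panel, sample_subset = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(sample_subset)) panel <- subset_panel(panel, samples = sample_subset)
  if (n_samples(panel) < 2L) stop_invalid("need >= 2 samples for a GRM")
  auto <- !is_x_chrom(panel$map$chrom)
  if (!any(auto)) stop_invalid("panel has no autosomal variants")
  panel <- subset_panel(panel, variants = which(auto))
  d <- panel$dosage
  p <- allele_freq(panel)
  usable <- !is.na(p) & p > 0 & p < 1
  denom <- sqrt(2 * p * (1 - p))
  z <- sweep(d, 2L, 2 * p, "-")
  z <- sweep(z, 2L, ifelse(usable, denom, 1), "/")
  obs <- !is.na(d)
  z[!obs] <- 0
  grm_from_scaled(z, obs, usable, panel$fam[, c("fid", "iid")],
                  source = "autosomal",
                  freq_basis = "analysis subset, both sexes combined")
}

#' X-chromosome GRM under a dosage-compensation model
#'
#' Female X dosages are standardized exactly as autosomal dosages,
#' `(x - 2p)/sqrt(2p(1-p))`.  Male hemizygous values in \{0, 1\} are coded
#' per model and centered at their expectation:
#' \describe{
#'   \item{FDC}{full dosage compensation — male dosage doubled,
#'     `(2x - 2p)/sqrt(2p(1-p))` (coded male variance 2 under HWE);}
#'   \item{NDC}{no dosage compensation — raw male dosage,
#'     `(x - p)/sqrt(2p(1-p))` (coded variance 1/2);}
#'   \item{EV}{equal variance — `(x - p)/sqrt(p(1-p))`, so male and female
#'     coded variances are both 1 under HWE.}
#' }
#' The allele frequency `p` counts males as a single allele:
#' `p = (sum female dosage + sum male dosage) / (2 n_f + n_m)`.
#'
#' @param panel a [genotype_panel()] containing X variants (chromosome 23).
#' @param sample_subset optional analysis-subset selector.
#' @param dc_model `"FDC"`, `"NDC"` or `"EV"`.
#' @return A `grm` object with `source = "X:<model>"`.
#' @export
x_grm <- function(panel, sample_subset = NULL, dc_model = c("FDC", "NDC", "EV")) {
  dc_model <- match.arg(dc_model)
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(sample_subset)) panel <- subset_panel(panel, samples = sample_subset)
  xv <- is_x_chrom(panel$map$chrom)
  if (!any(xv)) stop_invalid("panel has no X-chromosome variants")
  panel <- subset_panel(panel, variants = which(xv))
  if (n_samples(panel) < 2L) stop_invalid("need >= 2 samples for a GRM")
  d <- panel$dosage
  male <- panel$fam$sex == 1L
  p <- allele_freq(panel)
  usable <- !is.na(p) & p > 0 & p < 1
  z <- d
  # females: autosomal standardization
  if (any(!male)) {
    z[!male, ] <- sweep(d[!male, , drop = FALSE], 2L, 2 * p, "-")
    z[!male, ] <- sweep(z[!male, , drop = FALSE], 2L,
                        ifelse(usable, sqrt(2 * p * (1 - p)), 1), "/")
  }
  if (any(male)) {
    center <- switch(dc_model, FDC = 2 * p, NDC = p, EV = p)
    scale <- switch(dc_model,
                    FDC = sqrt(2 * p * (1 - p)),
                    NDC = sqrt(2 * p * (1 - p)),
                    EV = sqrt(p * (1 - p)))
    w <- if (dc_model == "FDC") 2 else 1
    z[male, ] <- sweep(w * d[male, , drop = FALSE], 2L, center, "-")
    z[male, ] <- sweep(z[male, , drop = FALSE], 2L,
                       ifelse(usable, scale, 1), "/")
  }
  obs <- !is.na(d)
  z[!obs] <- 0
  grm_from_scaled(z, obs, usable, panel$fam[, c("fid", "iid")],
                  source = paste0("X:", dc_model),
                  freq_basis = "analysis subset; males count one allele")
}

#' Select the X dosage-compensation model by restricted likelihood
#'
#' Fits the joint autosome + X REML model under each candidate X GRM and
#' returns the coding with the highest restricted log-likelihood.  Models
#' whose log-likelihood is within `tol` of the maximum are treated as tied
#' and resolved by the declared priority FDC > EV > NDC.
#'
#' @param y trait vector aligned with the GRM sample order.
#' @param covariates optional fixed-effect matrix (no intercept column).
#' @param auto_grm autosomal `grm`.
#' @param x_grms named list of X `grm`s, one per model (names `FDC`, `NDC`,
#'   `EV`); build them with [x_grm()].
#' @param tol log-likelihood tie tolerance.
#' @param ... passed to [fit_reml()].
#' @return A list with `model` (character), `table` (one row per candidate:
#'   model, logL, converged), and `fits` (the three REML fits).
#' @export
select_dc_model <- function(y, covariates = NULL, auto_grm, x_grms,
                            tol = 1e-8, ...) {
  stopifnot(is.list(x_grms), all(c("FDC", "NDC", "EV") %in% names(x_grms)))
  fits <- lapply(c("FDC", "NDC", "EV"), function(m) {
    fit_reml(y, covariates = covariates,
             grms = list(autosomal = auto_grm, x = x_grms[[m]]), ...)
  })
  names(fits) <- c("FDC", "NDC", "EV")
  table <- data.frame(model = names(fits),
                      logL = vapply(fits, function(f) f$logL, 0),
                      converged = vapply(fits, function(f) f$converged, TRUE),
                      stringsAsFactors = FALSE)
  if (!any(table$converged)) stop_invalid("REML failed to converge for every dosage-compensation model")
  best <- pick_dc_model(table, tol = tol)
  list(model = best, table = table, fits = fits)
}

# Tie-breaking rule, split out for direct testing: highest logL among
# converged fits; ties within tol resolved by priority FDC > EV > NDC.
pick_dc_model <- function(table, tol = 1e-8) {
  cand <- table[table$converged, , drop = FALSE]
  top <- max(cand$logL)
  tied <- cand$model[cand$logL >= top - tol]
  priority <- c("FDC", "EV", "NDC")
  priority[min(match(tied, priority))]
}

#' Prune related samples from a GRM
#'
#' Greedy removal until no kept pair has relatedness above `threshold`: at
#' each step the sample with the largest number of above-threshold partners
#' is removed; among ties, the sample occurring last in the GRM id order is
#' removed (earlier samples are kept).
#'
#' @param grm a `grm` object.
#' @param threshold relatedness ceiling (default 0.05).
#' @return Character vector of kept iids, in original order.
#' @export
prune_relatedness <- function(grm, threshold = 0.05) {
  stopifnot(inherits(grm, "grm"))
  a <- grm$grm
  diag(a) <- 0
  adj <- !is.na(a) & a > threshold
  keep <- rep(TRUE, nrow(a))
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (max(deg) == 0) break
    victim <- max(which(deg == max(deg)))  # ties: drop the later id
    keep[victim] <- FALSE
    adj[victim, ] <- FALSE
    adj[, victim] <- FALSE
  }
  grm$ids$iid[keep]
}

#' GCTA binary GRM triplet I/O
#'
#' `<prefix>.grm.bin` holds the lower triangle (diagonal included) of the
#' relationship matrix, row-major, as little-endian 4-byte floats;
#' `<prefix>.grm.N.bin` the per-pair usable-variant counts in the same
#' layout; `<prefix>.grm.id` the two-column FID/IID text file.
#'
#' @param grm a `grm` object.
#' @param prefix path prefix.
#' @return `write_gcta_grm` returns `prefix` invisibly; `read_gcta_grm`
#'   returns a `grm` (entries at float32 precision).
#' @export
write_gcta_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$grm)
  # row-major lower triangle including the diagonal
  idx <- sequence(seq_len(n))
  rows <- rep(seq_len(n), seq_len(n))
  vals <- grm$grm[cbind(rows, idx)]
  nvals <- grm$n_pairs[cbind(rows, idx)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(nvals), con, size = 4L, endian = "little")
  close(con)
  utils::write.table(grm$ids, paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_gcta_grm
#' @export
read_gcta_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)
  names(ids) <- c("fid", "iid")
  n <- nrow(ids)
  nv <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = nv, size = 4L,
                  endian = "little")
  nvals <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = nv, size = 4L,
                   endian = "little")
  if (length(vals) != nv) stop_invalid("GRM binary has %d entries, expected %d",
                                       length(vals), nv)
  mat <- matrix(0, n, n)
  npair <- matrix(0, n, n)
  idx <- sequence(seq_len(n))
  rows <- rep(seq_len(n), seq_len(n))
  mat[cbind(rows, idx)] <- vals
  npair[cbind(rows, idx)] <- nvals
  mat[upper.tri(mat)] <- t(mat)[upper.tri(mat)]
  npair[upper.tri(npair)] <- t(npair)[upper.tri(npair)]
  new_grm(mat, npair, ids, source = "file", freq_basis = "unknown (read from file)")
}
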