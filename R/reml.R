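#' Restricted maximum likelihood for GRM-structured variance components
#'
#' The model is `y ~ N(X b, sum_i V_Gi * GRM_i + V_E * I)`.  Estimation uses
#' average-information (AI) REML with a few initial EM steps and step-halving
#' whenever an AI update would decrease the restricted likelihood; variance
#' components are constrained non-negative by default (negative proposals are
#' reset to a small positive floor, as in GCTA).  The reported restricted
#' log-likelihood is `-(log|V| + log|X'V^-1 X| + y'Py)/2` (additive constants
#' dropped), so only differences between fits on the same data are
#' meaningful.
#'
#' @name reml
NULL

# ---- likelihood primitives ----------------------------------------------

# Restricted log-likelihood at fixed V (Cholesky-based, no explicit inverse).
loglik_V <- function(V, X, y, jitter = 0) {
  if (jitter > 0) diag(V) <- diag(V) + jitter
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  Vi_X <- backsolve(R, backsolve(R, X, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  R2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(R2)) return(-Inf)
  logdetB <- 2 * sum(log(diag(R2)))
  XtViy <- crossprod(X, Vi_y)
  yPy <- sum(y * Vi_y) - sum(XtViy * backsolve(R2, backsolve(R2, XtViy,
                                                             transpose = TRUE)))
  -0.5 * (logdetV + logdetB + yPy)
}

# Everything AI-REML needs at one parameter value: logL, score vector, AI
# matrix, and the projection ingredients.
reml_iteration <- function(V, dV, X, y) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Vi <- chol2inv(R)
  logdetV <- 2 * sum(log(diag(R)))
  XtVi <- crossprod(X, Vi)              # p x n
  XtViX <- XtVi %*% X
  R2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(R2)) return(NULL)
  logdetB <- 2 * sum(log(diag(R2)))
  Binv <- chol2inv(R2)
  P <- Vi - crossprod(XtVi, Binv %*% XtVi)
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  k <- length(dV)
  score <- numeric(k)
  Q <- matrix(0, n, k)
  for (i in seq_len(k)) {
    qi <- drop(dV[[i]] %*% Py)
    Q[, i] <- qi
    score[i] <- -0.5 * (sum(P * dV[[i]]) - sum(Py * qi))
  }
  AI <- 0.5 * crossprod(Q, P %*% Q)
  list(logL = -0.5 * (logdetV + logdetB + yPy),
       score = score, AI = symmetrize(AI), Py = Py, n = n)
}

# Active-set AI update: solve AI %*% delta = score; any constrained
# component whose proposal falls below its floor is pinned there and the
# system re-solved for the free parameters, so boundary components cannot
# freeze the rest of the update.
ai_step <- function(AI, score, theta, constrained, floor_val) {
  k <- length(score)
  solve_or_scale <- function(M, v) {
    out <- tryCatch(solve(M, v), error = function(e) NULL)
    if (is.null(out)) v / (abs(diag(M)) + 1e-8) else out
  }
  delta <- solve_or_scale(AI, score)
  for (pass in seq_len(k)) {
    active <- constrained & (theta + delta < floor_val)
    if (!any(active) || all(active)) break
    delta[active] <- floor_val - theta[active]
    free <- !active
    rhs <- score[free] - AI[free, active, drop = FALSE] %*% delta[active]
    delta[free] <- solve_or_scale(AI[free, free, drop = FALSE], drop(rhs))
  }
  delta
}

# ---- generic AI-REML driver ---------------------------------------------

# model: list(V_fun = function(theta) V, dV_fun = function(theta) list of
# derivative matrices, linear = TRUE/FALSE).  `vc` flags which parameters are
# variance components (floored at `floor_val` when constrain = TRUE).
ai_reml <- function(y, X, model, theta0, vc, constrain = TRUE,
                    max_iter = 100L, tol = 1e-6, n_em = 4L,
                    floor_val = NULL) {
  n <- length(y)
  if (qr(X)$rank < ncol(X)) stop_invalid("singular fixed-effect design")
  if (n <= ncol(X) + length(theta0)) {
    stop_invalid("need n > number of fixed effects + variance components")
  }
  if (is.null(floor_val)) floor_val <- 1e-6 * stats::var(y)
  clamp <- function(th) {
    if (constrain) th[vc] <- pmax(th[vc], floor_val)
    th
  }
  theta <- clamp(theta0)
  it <- NULL
  logL_prev <- -Inf
  converged <- FALSE
  iter_done <- 0L
  for (iter in seq_len(max_iter)) {
    it <- reml_iteration(model$V_fun(theta), model$dV_fun(theta), X, y)
    if (is.null(it)) {
      # non-PD at current theta: nudge components up and retry once
      theta[vc] <- theta[vc] + 10 * floor_val
      it <- reml_iteration(model$V_fun(theta), model$dV_fun(theta), X, y)
      if (is.null(it)) break
    }
    iter_done <- iter
    if (abs(it$logL - logL_prev) < tol) {
      converged <- TRUE
      break
    }
    logL_prev <- it$logL
    if (isTRUE(model$linear) && iter <= n_em) {
      # EM-REML update: theta_i + theta_i^2 (y'P dV P y - tr(P dV)) / n
      upd <- theta + theta^2 * (2 * it$score) / n
      theta <- clamp(upd)
      next
    }
    delta <- ai_step(it$AI, it$score, theta, vc & constrain, floor_val)
    step <- 1
    repeat {
      cand <- clamp(theta + step * delta)
      ll <- loglik_V(model$V_fun(cand), X, y)
      if (ll >= it$logL - 1e-8 || step < 1 / 64) break
      step <- step / 2
    }
    theta <- clamp(theta + step * delta)
  }
  if (is.null(it)) {
    return(list(theta = theta, cov = NULL, se = rep(NA_real_, length(theta)),
                logL = NA_real_, converged = FALSE, iterations = iter_done))
  }
  cov <- tryCatch(solve(it$AI), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, length(theta)) else sqrt(pmax(diag(cov), 0))
  list(theta = theta, cov = cov, se = se, logL = it$logL,
       converged = converged, iterations = iter_done,
       boundary = constrain & vc & theta <= floor_val * (1 + 1e-8))
}

as_grm_matrix <- function(g) {
  if (inherits(g, "grm")) g$grm else as.matrix(g)
}

# ---- univariate fit ------------------------------------------------------

#' Fit a univariate multi-GRM REML model
#'
#' @param y numeric trait vector.
#' @param covariates optional numeric matrix of fixed covariates (an
#'   intercept is always added).
#' @param grms a single `grm`/matrix or a (optionally named) list of them,
#'   all over the same samples in the same order as `y`.
#' @param constrain keep variance components non-negative (default `TRUE`;
#'   `FALSE` mirrors GCTA's `--reml-no-constrain`).
#' @param max_iter,tol iteration cap and `|delta logL|` convergence
#'   tolerance.
#' @param n_em number of initial EM steps before switching to AI updates.
#' @return An object of class `reml_fit` with elements `components` (named:
#'   one `V(G)` per GRM plus `V(e)`), `se`, `cov` (sampling covariance of
#'   the components), `Vp`, `h2` and `h2_se` (per-GRM and total, delta
#'   method), `logL`, `converged`, `iterations`, `n`.  Non-convergence is
#'   flagged, not raised.
#' @export
fit_reml <- function(y, covariates = NULL, grms, constrain = TRUE,
                     max_iter = 100L, tol = 1e-6, n_em = 4L) {
  y <- as.numeric(y)
  n <- length(y)
  if (inherits(grms, "grm") || is.matrix(grms)) grms <- list(grms)
  id_sets <- lapply(Filter(function(g) inherits(g, "grm"), grms),
                    function(g) g$ids$iid)
  if (length(id_sets) > 1L &&
      !all(vapply(id_sets[-1], identical, TRUE, id_sets[[1]]))) {
    stop_invalid("GRMs cover different samples (or a different order)")
  }
  A <- lapply(grms, as_grm_matrix)
  if (is.null(names(A)) || any(names(A) == "")) {
    names(A) <- paste0("G", seq_along(A))
  }
  for (a in A) {
    if (!is.matrix(a) || nrow(a) != n || ncol(a) != n) {
      stop_invalid("each GRM must be an %d x %d matrix aligned with y", n, n)
    }
    if (anyNA(a)) stop_invalid("GRM contains missing entries")
  }
  X <- build_design(n, covariates)
  dV <- c(A, list(diag(n)))
  k <- length(dV)
  model <- list(V_fun = function(th) {
                  V <- matrix(0, n, n)
                  for (i in seq_len(k)) V <- V + th[i] * dV[[i]]
                  V
                },
                dV_fun = function(th) dV,
                linear = TRUE)
  vp0 <- stats::var(y)
  theta0 <- c(rep(vp0 / (2 * length(A)), length(A)), vp0 / 2)
  res <- ai_reml(y, X, model, theta0, vc = rep(TRUE, k), constrain = constrain,
                 max_iter = max_iter, tol = tol, n_em = n_em)
  comp <- res$theta
  names(comp) <- c(paste0("V(", names(A), ")"), "V(e)")
  vp <- sum(comp)
  hs <- h2_from_components(comp, res$cov, n_genetic = length(A))
  structure(list(components = comp, se = stats::setNames(res$se, names(comp)),
                 cov = res$cov, Vp = vp,
                 h2 = hs$h2, h2_se = hs$se,
                 logL = res$logL, converged = res$converged,
                 iterations = res$iterations, n = n,
                 boundary = res$boundary, constrained = constrain),
            class = "reml_fit")
}

build_design <- function(n, covariates) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) stop_invalid("covariates must have one row per sample")
  cbind(1, covariates)
}

# Delta-method heritabilities from a component vector and its sampling
# covariance; h2_i = theta_i / sum(theta), plus the total over genetic terms.
h2_from_components <- function(comp, cov, n_genetic) {
  k <- length(comp)
  S <- sum(comp)
  if (S <= 0) stop_invalid("total phenotypic variance is not positive")
  h2 <- comp[seq_len(n_genetic)] / S
  tot <- sum(h2)
  grads <- lapply(seq_len(n_genetic), function(i) {
    g <- rep(-comp[i] / S^2, k)
    g[i] <- g[i] + 1 / S
    g
  })
  g_tot <- rep(-sum(comp[seq_len(n_genetic)]) / S^2, k)
  g_tot[seq_len(n_genetic)] <- g_tot[seq_len(n_genetic)] + 1 / S
  se <- rep(NA_real_, n_genetic + 1L)
  if (!is.null(cov)) {
    se[seq_len(n_genetic)] <- vapply(grads, function(g)
      sqrt(max(0, drop(t(g) %*% cov %*% g))), 0)
    se[n_genetic + 1L] <- sqrt(max(0, drop(t(g_tot) %*% cov %*% g_tot)))
  }
  nm <- c(names(comp)[seq_len(n_genetic)], "total")
  list(h2 = stats::setNames(c(h2, tot), nm), se = stats::setNames(se, nm))
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit (n = %d, %s, %d iterations, logL = %.4f)\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$logL))
  tab <- data.frame(Variance = x$components, SE = x$se)
  print(round(tab, 6))
  cat(sprintf("total h2 = %.4f (SE %.4f)\n",
              x$h2[["total"]], x$h2_se[["total"]]))
  invisible(x)
}

#' Heritability summary of a REML fit
#'
#' Per-component and total heritabilities with delta-method standard errors
#' computed from the full component sampling covariance.
#'
#' @param fit a `reml_fit`.
#' @return data.frame with columns source, variance, se, h2, h2_se, plus a
#'   `total` row (and a `V(e)` variance row with no h2).
#' @export
h2_summary <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$Vp <= 0) stop_invalid("invalid fit: Vp <= 0")
  ng <- length(fit$h2) - 1L
  data.frame(source = c(names(fit$components), "total"),
             variance = c(unname(fit$components), fit$Vp),
             se = c(unname(fit$se), NA),
             h2 = c(unname(fit$h2)[seq_len(ng)], NA, fit$h2[["total"]]),
             h2_se = c(unname(fit$h2_se)[seq_len(ng)], NA, fit$h2_se[["total"]]),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test
#'
#' `statistic = max(0, 2 (logL_full - logL_null))`; the p-value comes from a
#' chi-square with 1 df, or from the 50:50 mixture of a point mass at zero
#' and chi-square(1) when testing a variance component at its boundary
#' (`mixture = TRUE`).
#'
#' @param logL_full,logL_null restricted log-likelihoods of nested fits on
#'   the same data and fixed effects.
#' @param mixture use the boundary mixture null (default `FALSE`).
#' @return list with `statistic` and `p`.
#' @export
lrt <- function(logL_full, logL_null, mixture = FALSE) {
  stat <- pmax(0, 2 * (logL_full - logL_null))
  p_chi1 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p <- if (mixture) 0.5 * p_chi1 + 0.5 * (stat <= 0) else p_chi1
  list(statistic = stat, p = p)
}

#' Restricted log-likelihood at fixed variance components
#'
#' Evaluates the same criterion [fit_reml()] maximizes.  With a single GRM,
#' `method = "eigen"` uses the one-off eigendecomposition shortcut (`V` is
#' diagonal in the GRM eigenbasis), which is exact and much faster across
#' many component values.
#'
#' @param y trait vector.
#' @param covariates optional fixed-covariate matrix (intercept added).
#' @param grms GRM (or list of GRMs) as in [fit_reml()].
#' @param components numeric vector: one genetic variance per GRM, then the
#'   residual variance.
#' @param method `"direct"` (any number of GRMs) or `"eigen"` (single GRM).
#' @return The restricted log-likelihood (constants dropped).
#' @export
restricted_loglik <- function(y, covariates = NULL, grms, components,
                              method = c("direct", "eigen")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (inherits(grms, "grm") || is.matrix(grms)) grms <- list(grms)
  A <- lapply(grms, as_grm_matrix)
  if (length(components) != length(A) + 1L) {
    stop_invalid("'components' must hold one value per GRM plus the residual")
  }
  X <- build_design(n, covariates)
  if (method == "direct") {
    V <- diag(rep(components[length(components)], n))
    for (i in seq_along(A)) V <- V + components[i] * A[[i]]
    return(loglik_V(V, X, y))
  }
  if (length(A) != 1L) stop_invalid("'eigen' method requires a single GRM")
  e <- eigen(symmetrize(A[[1]]), symmetric = TRUE)
  yt <- drop(crossprod(e$vectors, y))
  Xt <- crossprod(e$vectors, X)
  d <- components[1] * e$values + components[2]
  if (any(d <= 0)) return(-Inf)
  XtViX <- crossprod(Xt, Xt / d)
  XtViy <- crossprod(Xt, yt / d)
  R2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(R2)) return(-Inf)
  yPy <- sum(yt^2 / d) - sum(XtViy * backsolve(R2, backsolve(R2, XtViy,
                                                             transpose = TRUE)))
  -0.5 * (sum(log(d)) + 2 * sum(log(diag(R2))) + yPy)
}

# ---- bivariate between-sex fit ------------------------------------------

#' Bivariate REML for the between-sex genetic correlation
#'
#' Treats the male and female measurements of one trait as two traits
#' observed on disjoint individuals over a combined-sex GRM (the
#' two-column-phenotype construction used with GCTA's `--reml-bivar`).
#' Estimated components are `V_Gm`, `V_Gf`, the cross-group genetic
#' covariance `C_G`, and the residual variances `V_Em`, `V_Ef`; the residual
#' cross-covariance is structurally zero because no individual carries both
#' traits.  `r_g = C_G / sqrt(V_Gm V_Gf)` with a delta-method SE, and the
#' deviation from `r_g = 1` is assessed by refitting under the constraint
#' `C_G = sqrt(V_Gm V_Gf)` and a 1-df likelihood-ratio test (the
#' `--reml-bivar-rg 1` analogue).
#'
#' @param y_male,y_female named numeric vectors (names = iid); every GRM
#'   sample must appear in exactly one of the two.
#' @param covariates optional numeric matrix with rownames = iid; each
#'   column enters with a separate coefficient per sex.
#' @param grm combined-sex `grm` (or plain matrix, in which case `ids` must
#'   give the sample order).
#' @param ids character sample order when `grm` is a plain matrix.
#' @param max_iter,tol as in [fit_reml()].
#' @return An object of class `bivar_fit`: components and SEs, `rg`,
#'   `rg_se`, `logL` (unconstrained), `logL_rg1`, `lrt_rg1` (statistic and
#'   p), convergence and stability flags, per-group sample sizes.
#' @export
fit_bivariate <- function(y_male, y_female, covariates = NULL, grm,
                          ids = NULL, max_iter = 100L, tol = 1e-6) {
  if (inherits(grm, "grm")) {
    ids <- grm$ids$iid
    A <- grm$grm
  } else {
    A <- as.matrix(grm)
    if (is.null(ids)) stop_invalid("'ids' is required when 'grm' is a plain matrix")
  }
  n <- length(ids)
  in_m <- ids %in% names(y_male)
  in_f <- ids %in% names(y_female)
  if (any(in_m & in_f) || !all(in_m | in_f)) {
    stop_invalid("every GRM sample must appear in exactly one of y_male / y_female")
  }
  y <- numeric(n)
  y[in_m] <- y_male[ids[in_m]]
  y[in_f] <- y_female[ids[in_f]]
  mvec <- as.numeric(in_m)
  fvec <- as.numeric(in_f)
  # sex-specific intercepts, and per-sex coefficients for each covariate
  X <- cbind(mvec, fvec)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates))) {
      if (nrow(covariates) != n) stop_invalid("covariates need rownames or GRM order")
    } else {
      covariates <- covariates[ids, , drop = FALSE]
    }
    X <- cbind(X, covariates * mvec, covariates * fvec)
  }
  B1 <- A * tcrossprod(mvec)
  B2 <- A * tcrossprod(fvec)
  B3 <- A * (tcrossprod(mvec, fvec) + tcrossprod(fvec, mvec))
  B4 <- diag(mvec)
  B5 <- diag(fvec)
  dV <- list(B1, B2, B3, B4, B5)
  model <- list(V_fun = function(th) th[1] * B1 + th[2] * B2 + th[3] * B3 +
                  th[4] * B4 + th[5] * B5,
                dV_fun = function(th) dV,
                linear = TRUE)
  vm <- stats::var(y[in_m])
  vf <- stats::var(y[in_f])
  theta0 <- c(vm / 2, vf / 2, 0.25 * sqrt(vm * vf), vm / 2, vf / 2)
  vc <- c(TRUE, TRUE, FALSE, TRUE, TRUE)   # C_G free in sign
  floor_val <- 1e-6 * max(vm, vf)
  res <- ai_reml(y, X, model, theta0, vc = vc, constrain = TRUE,
                 max_iter = max_iter, tol = tol, n_em = 4L,
                 floor_val = floor_val)
  comp <- stats::setNames(res$theta, c("V_Gm", "V_Gf", "C_G", "V_Em", "V_Ef"))
  rg <- comp[["C_G"]] / sqrt(comp[["V_Gm"]] * comp[["V_Gf"]])
  rg_se <- NA_real_
  if (!is.null(res$cov)) {
    g <- c(-rg / (2 * comp[["V_Gm"]]), -rg / (2 * comp[["V_Gf"]]),
           1 / sqrt(comp[["V_Gm"]] * comp[["V_Gf"]]), 0, 0)
    rg_se <- sqrt(max(0, drop(t(g) %*% res$cov %*% g)))
  }
  # constrained refit: C_G = sqrt(V_Gm V_Gf)  (r_g = 1)
  con_model <- list(
    V_fun = function(th) th[1] * B1 + th[2] * B2 +
      sqrt(th[1] * th[2]) * B3 + th[3] * B4 + th[4] * B5,
    dV_fun = function(th) list(
      B1 + 0.5 * sqrt(th[2] / th[1]) * B3,
      B2 + 0.5 * sqrt(th[1] / th[2]) * B3,
      B4, B5),
    linear = FALSE)
  th_start <- pmax(c(comp[["V_Gm"]], comp[["V_Gf"]], comp[["V_Em"]],
                     comp[["V_Ef"]]), floor_val)
  con <- ai_reml(y, X, con_model, th_start, vc = rep(TRUE, 4L),
                 constrain = TRUE, max_iter = max_iter, tol = tol,
                 n_em = 0L, floor_val = floor_val)
  test <- lrt(res$logL, con$logL, mixture = FALSE)
  unstable <- isTRUE(any(res$boundary[1:2])) ||
    comp[["V_Gm"]] <= floor_val * 1.01 || comp[["V_Gf"]] <= floor_val * 1.01
  structure(list(components = comp,
                 se = stats::setNames(res$se, names(comp)),
                 cov = res$cov,
                 rg = unname(rg), rg_se = rg_se,
                 logL = res$logL, logL_rg1 = con$logL,
                 lrt_rg1 = test,
                 converged = res$converged, converged_rg1 = con$converged,
                 unstable = unstable,
                 n_male = sum(in_m), n_female = sum(in_f)),
            class = "bivar_fit")
}

#' @export
print.bivar_fit <- function(x, ...) {
  cat(sprintf("bivariate REML (n_m = %d, n_f = %d, %s)\n", x$n_male,
              x$n_female, if (x$converged) "converged" else "NOT converged"))
  print(round(data.frame(Variance = x$components, SE = x$se), 6))
  cat(sprintf("r_g = %.4f (SE %.4f); LRT r_g = 1: stat %.3f, p = %.4g\n",
              x$rg, x$rg_se, x$lrt_rg1$statistic, x$lrt_rg1$p))
  invisible(x)
}

#' Write a GCTA-style .hsq result table
#'
#' @param fit a `reml_fit`.
#' @param file output path.
#' @param logL_null optional null log-likelihood for the LRT rows (boundary
#'   mixture).
#' @export
write_hsq <- function(fit, file, logL_null = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  ng <- length(fit$components) - 1L
  rows <- character(0)
  add <- function(...) rows <<- c(rows, paste(..., sep = "\t"))
  add("Source", "Variance", "SE")
  for (i in seq_len(ng)) {
    add(names(fit$components)[i], format(fit$components[i]), format(fit$se[i]))
  }
  add("V(e)", format(fit$components[ng + 1L]), format(fit$se[ng + 1L]))
  add("Vp", format(fit$Vp), "")
  for (i in seq_len(ng)) {
    add(paste0(names(fit$components)[i], "/Vp"), format(fit$h2[i]),
        format(fit$h2_se[i]))
  }
  add("Sum of V(G)/Vp", format(fit$h2[["total"]]), format(fit$h2_se[["total"]]))
  add("logL", format(fit$logL), "")
  if (!is.null(logL_null)) {
    tst <- lrt(fit$logL, logL_null, mixture = TRUE)
    add("LRT", format(tst$statistic), "")
    add("Pval", format(tst$p), "")
  }
  add("n", format(fit$n), "")
  writeLines(rows, file)
  invisible(file)
}
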