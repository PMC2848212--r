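# Poisson multilevel multiple-membership models for small-area counts.
#
# O_i ~ Poisson(mu_i),  log mu_i = log E_i + alpha + x_i' beta
#                                  + u_i + sum_j z_ij v*_j + w_k(i)
#
# u_i: unstructured municipality heterogeneity, N(0, sigma2_u)
# v*_j: latent effect of municipality j on its neighborhood; the spatial
#       (clustering) effect of area i is the Z-weighted sum of the v*_j of
#       all areas within the dependency radius, v = Z v*, v* ~ N(0, sigma2_v I)
# w_k: optional third-level effect (health district in Model B,
#       environmental risk area in Model C), N(0, sigma2_w)
# All cross-covariances between the random-effect vectors are fixed at zero.
#
# Estimation: Laplace-approximated marginal maximum likelihood. The combined
# random-effect design T = [I, Z, A] is sparse; the inner loop locates the
# joint conditional mode of (u, v*, w) by damped Newton steps, the outer
# optimizer moves (alpha, beta, log sigma2) against the Laplace objective
#   lnL = lnf(y | b_hat) - b_hat' P b_hat / 2 + log det(P)/2 - log det(H)/2
# with P the prior precision and H = T' diag(mu) T + P the conditional
# negative Hessian. Variances are optimized on the log scale with a floor;
# a variance stuck at the floor is refit fixed at exactly zero (for the
# clustering variance this sets the `clustering_variance_floored` flag,
# mirroring the classical treatment of negative variance estimates).

#' Estimation options for [fit_poisson_mmm()]
#'
#' @param max_outer Maximum outer optimizer iterations.
#' @param max_inner Maximum Newton iterations for the conditional modes.
#' @param rel_tol Relative convergence tolerance on the Laplace
#'   log-likelihood in the outer optimizer.
#' @param inner_tol Gradient tolerance for the conditional-mode Newton loop.
#' @param variance_floor Lower bound for variances during optimization; an
#'   estimate at the floor is treated as zero and the model refit.
#' @param start_sigma2 Deterministic starting value for every variance.
#' @return List of class `"mmm_control"`.
#' @export
mmm_control <- function(max_outer = 500, max_inner = 100, rel_tol = 1e-10,
                        inner_tol = 1e-9, variance_floor = 1e-8,
                        start_sigma2 = 0.1) {
  structure(list(max_outer = max_outer, max_inner = max_inner,
                 rel_tol = rel_tol, inner_tol = inner_tol,
                 variance_floor = variance_floor,
                 start_sigma2 = start_sigma2),
            class = "mmm_control")
}

#' Fit a Poisson multiple-membership multilevel model
#'
#' Fits one of the three rate-smoothing model variants by Laplace
#' marginal maximum likelihood:
#' \describe{
#'   \item{A}{heterogeneity + spatial multiple-membership effect;}
#'   \item{B}{A plus a health-district (ASL) random effect;}
#'   \item{C}{A plus an environmental-risk-area random effect (areas outside
#'     every risk zone form their own group).}
#' }
#' For variants B and C the structure's `third_level` labels supply the
#' grouping. Variance components are reported with standard errors (delta
#' method from the observed information) and Wald p-values (two-sided by
#' default; see [wald_variance_pvalue()]).
#'
#' @param observed Observed cases `O_i` per area.
#' @param expected Expected cases `E_i` per area (all > 0), typically from
#'   [fit_risk_model()]; `log(E_i)` enters as the offset.
#' @param structure A `"membership_structure"` for the same areas.
#' @param variant `"A"`, `"B"` or `"C"`.
#' @param covariates Optional numeric matrix of area-level covariates
#'   (fixed effects beta); default none.
#' @param pvalue_sides 2 (default) or 1: sidedness of the variance Wald
#'   p-values.
#' @param control A [mmm_control()] list.
#' @return Object of class `"mmm_fit"`; see Details for the main fields:
#'   `alpha`, `beta`, `sigma2` (named vector `u`, `v`, and `w` for B/C),
#'   `sigma2_se`, `sigma2_p`, conditional modes `u`, `v_star`, `w`, per-area
#'   spatial effect `v`, `fitted_rr`, `fitted_mu`, `log_likelihood`, `aic`,
#'   `k`, `convergence` (0 = converged), and the
#'   `clustering_variance_floored` flag.
#' @export
fit_poisson_mmm <- function(observed, expected, structure,
                            variant = c("A", "B", "C"), covariates = NULL,
                            pvalue_sides = 2, control = mmm_control()) {
  variant <- match.arg(variant)
  y <- as.numeric(observed)
  E <- as.numeric(expected)
  n <- length(y)
  stopifnot(inherits(structure, "membership_structure"),
            length(E) == n, nrow(structure$Z) == n)
  if (any(E <= 0)) stop("all expected counts must be positive (log offset)")
  if (any(y < 0) || any(y != round(y))) stop("observed counts must be non-negative integers")

  X <- NULL
  if (!is.null(covariates)) {
    X <- as.matrix(covariates)
    stopifnot(nrow(X) == n)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }

  blocks <- list(u = Matrix::Diagonal(n), v = structure$Z)
  groups <- NULL
  if (variant %in% c("B", "C")) {
    if (is.null(structure$third_level)) {
      stop("variant ", variant, " requires third-level labels in the structure")
    }
    groups <- droplevels(structure$third_level)
    K <- nlevels(groups)
    if (K >= n) {
      stop("unidentifiable: third level has as many groups as areas")
    }
    blocks$w <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(groups),
                                     x = 1, dims = c(n, K))
  }

  fit <- mmm_fit_blocks(y, E, X, blocks, control)

  # flooring / refit rule: variances stuck at the floor are fixed at zero
  floored <- stats::setNames(rep(FALSE, length(blocks)), names(blocks))
  while (any(fit$sigma2 <= 100 * control$variance_floor & !floored[names(fit$sigma2)])) {
    hit <- names(fit$sigma2)[fit$sigma2 <= 100 * control$variance_floor]
    floored[hit] <- TRUE
    keep <- blocks[setdiff(names(blocks), names(floored)[floored])]
    fit <- mmm_fit_blocks(y, E, X, keep, control)
    if (length(keep) == 0L) break
  }

  # assemble reported components (floored ones as exact zeros, SE absent)
  comp <- names(blocks)
  sigma2 <- stats::setNames(rep(0, length(comp)), comp)
  sigma2_se <- stats::setNames(rep(NA_real_, length(comp)), comp)
  active <- setdiff(comp, comp[floored[comp]])
  sigma2[active] <- fit$sigma2[active]
  sigma2_se[active] <- fit$sigma2_se[active]
  sigma2_p <- mapply(function(est, se) {
    if (is.na(se) || se <= 0) NA_real_ else wald_variance_pvalue(est, se, pvalue_sides)
  }, sigma2, sigma2_se)

  q_split <- split_modes(fit$b, fit$blocks, n, groups)
  v <- as.vector(structure$Z %*% q_split$v_star)
  w_area <- if (is.null(groups)) rep(0, n) else q_split$w[as.integer(groups)]
  eta_fix <- fit$alpha + if (is.null(X)) 0 else as.vector(X %*% fit$beta)
  fitted_rr <- exp(eta_fix + q_split$u + v + w_area)

  k <- 1L + (if (is.null(X)) 0L else ncol(X)) + length(active)
  out <- list(
    variant = variant, alpha = fit$alpha, alpha_se = fit$alpha_se,
    beta = fit$beta, beta_se = fit$beta_se,
    sigma2 = sigma2, sigma2_se = sigma2_se, sigma2_p = sigma2_p,
    pvalue_sides = pvalue_sides,
    u = q_split$u, v_star = q_split$v_star, w = q_split$w, v = v,
    w_area = w_area,
    fitted_rr = fitted_rr, fitted_mu = E * fitted_rr,
    log_likelihood = fit$log_likelihood, k = k,
    aic = 2 * k - 2 * fit$log_likelihood,
    convergence = fit$convergence, iterations = fit$iterations,
    clustering_variance_floored = unname(floored["v"]),
    floored = floored,
    observed = y, expected = E, covariates = X,
    n_areas = n, groups = groups,
    n_bar = structure$n_bar, m_bar = structure$m_bar,
    control = control)
  class(out) <- "mmm_fit"
  out
}

split_modes <- function(b, blocks, n, groups) {
  sizes <- vapply(blocks, ncol, numeric(1))
  idx <- split(seq_along(b), rep(names(blocks), sizes))
  u <- if ("u" %in% names(blocks)) b[idx$u] else rep(0, n)
  v_star <- if ("v" %in% names(blocks)) b[idx$v] else rep(0, n)
  w <- if ("w" %in% names(blocks)) {
    stats::setNames(b[idx$w], levels(groups))
  } else if (!is.null(groups)) {
    stats::setNames(rep(0, nlevels(groups)), levels(groups))
  } else numeric(0)
  list(u = u, v_star = v_star, w = w)
}

# Core fitter for a given set of random-effect design blocks.
mmm_fit_blocks <- function(y, E, X, blocks, control) {
  n <- length(y)
  logE <- log(E)
  p <- if (is.null(X)) 0L else ncol(X)
  nc <- length(blocks)

  if (nc == 0L) {
    # pure fixed-effect Poisson fit with offset
    fit0 <- if (p) {
      stats::glm(y ~ . + offset(logE), data = as.data.frame(X),
                 family = stats::poisson())
    } else {
      stats::glm(y ~ 1 + offset(logE), family = stats::poisson())
    }
    cf <- stats::coef(fit0); se <- sqrt(diag(stats::vcov(fit0)))
    ll <- as.numeric(stats::logLik(fit0))
    return(list(alpha = unname(cf[1]), alpha_se = unname(se[1]),
                beta = if (p) cf[-1] else NULL,
                beta_se = if (p) se[-1] else NULL,
                sigma2 = stats::setNames(numeric(0), character(0)),
                sigma2_se = stats::setNames(numeric(0), character(0)),
                b = numeric(0), blocks = blocks, log_likelihood = ll,
                convergence = 0L, iterations = 0L))
  }

  Tm <- do.call(cbind, lapply(blocks, methods::as, "CsparseMatrix"))
  sizes <- vapply(blocks, ncol, integer(1))
  q <- sum(sizes)
  env <- new.env()
  env$b <- rep(0, q)

  laplace <- function(par) {
    fixed <- par[seq_len(1 + p)]
    s2 <- exp(par[-seq_len(1 + p)])
    prec <- rep(1 / s2, sizes)
    eta0 <- logE + fixed[1] + if (p) as.vector(X %*% fixed[-1]) else 0
    b <- env$b
    joint <- function(b, eta, mu) -sum(y * eta - mu) + 0.5 * sum(prec * b^2)
    eta <- eta0 + as.vector(Tm %*% b)
    mu <- exp(eta)
    if (!all(is.finite(mu))) { b <- rep(0, q); eta <- eta0; mu <- exp(eta) }
    if (!all(is.finite(mu))) return(1e10)
    f <- joint(b, eta, mu)
    H <- NULL
    for (it in seq_len(control$max_inner)) {
      g <- as.vector(Matrix::crossprod(Tm, mu - y)) + prec * b
      H <- Matrix::forceSymmetric(Matrix::crossprod(Tm, Tm * mu)) +
        Matrix::Diagonal(q, prec)
      Ch <- Matrix::Cholesky(H, LDL = TRUE)
      step <- as.vector(Matrix::solve(Ch, g))
      tt <- 1
      repeat {
        bn <- b - tt * step
        etan <- eta0 + as.vector(Tm %*% bn)
        mun <- exp(etan)
        fn <- if (all(is.finite(mun))) joint(bn, etan, mun) else Inf
        if (fn <= f + 1e-12) break
        tt <- tt / 2
        if (tt < 1e-10) { bn <- b; etan <- eta; mun <- mu; fn <- f; break }
      }
      done <- max(abs(g)) < control$inner_tol ||
        abs(f - fn) < 1e-13 * (abs(f) + 1)
      b <- bn; eta <- etan; mu <- mun; f <- fn
      if (done) break
    }
    env$b <- b
    H <- Matrix::forceSymmetric(Matrix::crossprod(Tm, Tm * mu)) +
      Matrix::Diagonal(q, prec)
    ldetH <- as.numeric(Matrix::determinant(H, logarithm = TRUE)$modulus)
    ll <- sum(y * eta - mu - lgamma(y + 1)) - 0.5 * sum(prec * b^2) +
      0.5 * sum(log(prec)) - 0.5 * ldetH
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  alpha0 <- log(sum(y) / sum(E))
  par0 <- c(alpha0, rep(0, p), rep(log(control$start_sigma2), nc))
  lower <- c(rep(-Inf, 1 + p), rep(log(control$variance_floor), nc))
  upper <- c(rep(Inf, 1 + p), rep(6, nc))
  opt <- stats::nlminb(par0, laplace, lower = lower, upper = upper,
                       control = list(rel.tol = control$rel_tol,
                                      iter.max = control$max_outer,
                                      eval.max = 4 * control$max_outer))

  # observed-information standard errors in (alpha, beta, log sigma2),
  # mapped to the natural variance scale by the delta method
  hess <- try(pracma::hessian(laplace, opt$par), silent = TRUE)
  se_all <- rep(NA_real_, length(opt$par))
  if (!inherits(hess, "try-error")) {
    cov_try <- try(solve(hess), silent = TRUE)
    if (!inherits(cov_try, "try-error")) {
      dvar <- diag(cov_try)
      if (all(is.finite(dvar)) && all(dvar > 0)) se_all <- sqrt(dvar)
    }
  }
  s2_hat <- exp(opt$par[-seq_len(1 + p)])
  se_s2 <- se_all[-seq_len(1 + p)] * s2_hat  # delta: SE(s2) = s2 * SE(log s2)

  laplace(opt$par)  # restore conditional modes at the optimum

  list(alpha = opt$par[1], alpha_se = se_all[1],
       beta = if (p) stats::setNames(opt$par[2:(1 + p)], colnames(X)) else NULL,
       beta_se = if (p) stats::setNames(se_all[2:(1 + p)], colnames(X)) else NULL,
       sigma2 = stats::setNames(s2_hat, names(blocks)),
       sigma2_se = stats::setNames(se_s2, names(blocks)),
       b = env$b, blocks = blocks,
       log_likelihood = -opt$objective,
       convergence = opt$convergence, iterations = opt$iterations)
}

#' One- or two-sided Wald p-value for a variance component
#'
#' `p = 1 - pnorm(estimate / se)` (one-sided, the default here) or
#' `p = 2 * (1 - pnorm(|estimate| / se))` (two-sided, the default used when
#' reporting fits, which matches how such p-values are conventionally
#' tabulated alongside variance estimates).
#'
#' @param estimate Variance estimate.
#' @param se Its standard error (> 0).
#' @param sides 1 or 2.
#' @return The p-value, or `NA` when `se` is not positive.
#' @export
wald_variance_pvalue <- function(estimate, se, sides = 1) {
  if (!is.numeric(se) || is.na(se) || se <= 0) return(NA_real_)
  z <- estimate / se
  if (sides == 1) stats::pnorm(z, lower.tail = FALSE)
  else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Conditional modes of the random effects
#'
#' Extracts the conditional modes `u_i`, `v*_j`, `w_k` of a converged fit
#' and recomputes the per-area spatial effect `v = Z v*` through the weight
#' matrix of the supplied structure.
#'
#' @param fit An `"mmm_fit"`.
#' @param structure The `"membership_structure"` the model was fitted with.
#' @return List with `u`, `v_star`, `w` (named by group) and `v`.
#' @export
predict_random_effects <- function(fit, structure) {
  stopifnot(inherits(fit, "mmm_fit"), inherits(structure, "membership_structure"))
  if (fit$convergence != 0) stop("fit did not converge; refusing predictions")
  list(u = fit$u, v_star = fit$v_star, w = fit$w,
       v = as.vector(structure$Z %*% fit$v_star))
}

#' Rank fitted models by AIC
#'
#' Builds the model-comparison table (variant, number of estimated
#' parameters k, maximized log-likelihood, AIC = 2k - 2 lnL) sorted by AIC,
#' lower k winning ties. All fits must be on identical data (same observed
#' and expected counts).
#'
#' @param ... `"mmm_fit"` objects, or a single list of them.
#' @return Data frame sorted by AIC with columns `variant`, `k`, `logLik`,
#'   `AIC`, `converged`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "mmm_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "mmm_fit")))
  ref <- fits[[1]]
  for (f in fits[-1]) {
    if (!isTRUE(all.equal(f$observed, ref$observed)) ||
        !isTRUE(all.equal(f$expected, ref$expected))) {
      stop("models were fitted on different data; AIC comparison is invalid")
    }
  }
  tab <- data.frame(
    variant = vapply(fits, `[[`, character(1), "variant"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    AIC = vapply(fits, `[[`, numeric(1), "aic"),
    converged = vapply(fits, function(f) f$convergence == 0, logical(1)))
  tab[order(tab$AIC, tab$k), , drop = FALSE]
}

#' @export
logLik.mmm_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, class = "logLik")
}

#' @export
print.mmm_fit <- function(x, digits = 4, ...) {
  lab <- c(A = "spatial effect",
           B = "spatial + health-district (ASL) effect",
           C = "spatial + environmental-risk-area effect")
  cat(sprintf("Poisson multiple-membership model %s (%s)\n", x$variant,
              lab[x$variant]))
  cat(sprintf("  areas: %d   logLik: %.2f   k: %d   AIC: %.1f\n",
              x$n_areas, x$log_likelihood, x$k, x$aic))
  cat(sprintf("  intercept: %.4f (SE %.4f)\n", x$alpha, x$alpha_se))
  if (!is.null(x$beta)) {
    for (nm in names(x$beta)) {
      cat(sprintf("  beta[%s]: %.4f (SE %.4f)\n", nm, x$beta[nm], x$beta_se[nm]))
    }
  }
  comp_lab <- c(u = "sigma2_u (heterogeneity)", v = "sigma2_v (clustering)",
                w = "sigma2_w (third level)")
  for (nm in names(x$sigma2)) {
    se <- x$sigma2_se[nm]
    cat(sprintf("  %-26s %.4f%s\n", comp_lab[nm], x$sigma2[nm],
                if (is.na(se)) "  (fixed at zero)" else
                  sprintf(" (SE %.4f, p %s)", se,
                          format.pval(x$sigma2_p[nm], digits = 3))))
  }
  if (isTRUE(x$clustering_variance_floored)) {
    cat("  note: clustering variance floored at zero and model refit\n")
  }
  if (x$convergence != 0) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}
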