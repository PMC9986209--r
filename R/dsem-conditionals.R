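# Exact full-conditional building blocks of the Gibbs sampler, exposed as
# plain R functions. `run_mcmc()` uses a compiled equivalent of the
# within-person steps for speed; these reference implementations define the
# contracts and are what the oracle tests exercise.

# Bivariate normal log-density with precomputed Cholesky-free 2x2 algebra.
ldmvnorm2 <- function(x, mean, sigma) {
  d <- x - mean
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
  if (det_s <= 0) abort("Singular innovation covariance.")
  q <- (d[1]^2 * sigma[2, 2] - 2 * d[1] * d[2] * sigma[1, 2] +
          d[2]^2 * sigma[1, 1]) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

#' Within-person transition log-likelihood
#'
#' Log-density of a person's latent lag-1 process: the sum over transitions of
#' `log N(x_t; Phi x_{t-1}, sigma_w)`, where the deviations `x_t` are the
#' observations minus the person's means.
#'
#' @param y complete T x 2 matrix (columns stress, affect) on the observed
#'   scale.
#' @param re named random-effect vector (`mu_s`, `mu_a`, `phi_ss`, `phi_aa`,
#'   `phi_as`, `phi_sa`).
#' @param sigma_w 2 x 2 innovation covariance.
#' @return Scalar log-likelihood over the `T - 1` transitions (the first
#'   observation is conditioned on).
#' @export
within_loglik <- function(y, re, sigma_w) {
  y <- as.matrix(y)
  stopifnot(ncol(y) == 2, nrow(y) >= 2, !anyNA(y))
  phi <- phi_matrix(re)
  x <- sweep(y, 2, c(re[["mu_s"]], re[["mu_a"]]))
  ll <- 0
  for (t in 2:nrow(x)) {
    ll <- ll + ldmvnorm2(x[t, ], as.numeric(phi %*% x[t - 1, ]), sigma_w)
  }
  ll
}

#' Impute latent states at missing grid slots
#'
#' One Gibbs sweep of exact per-slot full-conditional draws over the missing
#' cells of a person's aligned series, given the person's dynamics. Interior
#' missing slots are conditioned on both neighbours; leading missing slots use
#' the stationary distribution as initial prior; trailing missing slots are
#' forecast from the left neighbour. Partially missing slots (one of the two
#' variables observed) are conditioned on the observed component as well.
#'
#' @param y T x 2 matrix with `NA` at missing cells (observed scale).
#' @param re named random-effect vector.
#' @param sigma_w innovation covariance.
#' @param sweeps number of full sweeps (consecutive missing runs mix across
#'   sweeps).
#' @return The completed T x 2 matrix.
#' @export
sample_latent_states <- function(y, re, sigma_w, sweeps = 1) {
  y <- as.matrix(y)
  stopifnot(ncol(y) == 2)
  if (all(is.na(y))) abort("At least one observed cell is required.")
  phi <- phi_matrix(re)
  mu <- c(re[["mu_s"]], re[["mu_a"]])
  W <- solve(sigma_w)
  T_n <- nrow(y)
  miss <- is.na(y)
  if (!any(miss)) return(y)
  s0 <- if (spectral_radius(phi) < 1) stationary_cov(phi, sigma_w) else
    diag(1e6, 2)
  s0_inv <- solve(s0)
  # initialise missing cells at the person mean
  y[ , 1][miss[, 1]] <- mu[1]
  y[ , 2][miss[, 2]] <- mu[2]
  x <- sweep(y, 2, mu)

  first_obs <- min(which(rowSums(!miss) > 0))
  for (s in seq_len(sweeps)) {
    for (t in seq_len(T_n)) {
      if (!any(miss[t, ])) next
      has_left <- t > 1
      has_right <- t < T_n
      P <- matrix(0, 2, 2); b <- c(0, 0)
      if (has_left) {
        P <- P + W
        b <- b + W %*% (phi %*% x[t - 1, ])
      } else {
        P <- P + s0_inv                       # stationary initial prior
      }
      if (has_right) {
        P <- P + t(phi) %*% W %*% phi
        b <- b + t(phi) %*% (W %*% x[t + 1, ])
      }
      V <- solve(P)
      m <- as.numeric(V %*% b)
      if (all(miss[t, ])) {
        x[t, ] <- rmvnorm_chol(1, m, V)
      } else {
        j <- which(miss[t, ]); k <- 3 - j
        cm <- m[j] + V[j, k] / V[k, k] * (x[t, k] - m[k])
        cv <- V[j, j] - V[j, k]^2 / V[k, k]
        x[t, j] <- rnorm(1, cm, sqrt(max(cv, 0)))
      }
    }
  }
  out <- sweep(x, 2, mu, `+`)
  out[!miss] <- as.matrix(y)[!miss]
  out
}

#' Draw a person's random effects from their full conditional
#'
#' Conjugate normal draws of the person-specific means and transition
#' coefficients given a completed series and the between-level prior
#' (whose mean is `intercept + gamma * ADHD + covariate terms`, supplied by
#' the caller as `prior_mean`). With fewer than two usable transitions the
#' draw falls back to the prior, with a message.
#'
#' @param y complete T x 2 matrix on the observed scale.
#' @param prior_mean,prior_var named 6-vectors (see [true_model()] for names).
#' @param sigma_w innovation covariance.
#' @param current named 6-vector of current values (defaults to `prior_mean`);
#'   the mean block is drawn given the current transition block and vice
#'   versa.
#' @param blocks which blocks to update: `"mu"`, `"phi"` or both.
#' @return A named 6-vector draw.
#' @export
sample_random_effects <- function(y, prior_mean, prior_var, sigma_w,
                                  current = NULL, blocks = c("mu", "phi")) {
  rn <- re_names()
  prior_mean <- prior_mean[rn]; prior_var <- prior_var[rn]
  re <- (current %||% prior_mean)[rn]
  y <- as.matrix(y)
  if (nrow(y) < 3) {
    message("Fewer than 2 usable transitions; drawing from the prior.")
    return(stats::setNames(rnorm(6, prior_mean, sqrt(prior_var)), rn))
  }
  W <- solve(sigma_w)
  n_tr <- nrow(y) - 1

  if ("mu" %in% blocks) {
    phi <- phi_matrix(re)
    D <- diag(2) - phi
    g <- t(y[-1, , drop = FALSE]) - phi %*% t(y[-nrow(y), , drop = FALSE])
    P <- n_tr * (t(D) %*% W %*% D) + diag(1 / prior_var[c("mu_s", "mu_a")])
    b <- t(D) %*% (W %*% rowSums(g)) +
      prior_mean[c("mu_s", "mu_a")] / prior_var[c("mu_s", "mu_a")]
    re[c("mu_s", "mu_a")] <- draw_gaussian_natural(P, as.numeric(b))
  }

  if ("phi" %in% blocks) {
    th_names <- c("phi_ss", "phi_as", "phi_sa", "phi_aa")
    x <- sweep(y, 2, re[c("mu_s", "mu_a")])
    xl <- x[-nrow(x), , drop = FALSE]
    xr <- x[-1, , drop = FALSE]
    Sxx <- crossprod(xl)
    Sxy <- crossprod(xl, xr)
    P <- rbind(cbind(W[1, 1] * Sxx, W[1, 2] * Sxx),
               cbind(W[2, 1] * Sxx, W[2, 2] * Sxx)) +
      diag(1 / prior_var[th_names])
    b <- c(Sxy %*% W[, 1], Sxy %*% W[, 2]) +
      prior_mean[th_names] / prior_var[th_names]
    re[th_names] <- draw_gaussian_natural(P, b)
  }
  re[rn]
}

# Conjugate normal draw of regression coefficients given the residual
# variance, with independent N(0, 1/prec_j) priors per coefficient.
# `prec` recycles to ncol(X); pass c(intercept_prec, slope_precs...).
draw_reg <- function(X, y, resid_var, prec = 1e-6) {
  P <- crossprod(X) / resid_var + diag(rep_len(prec, ncol(X)), ncol(X))
  b <- crossprod(X, y) / resid_var
  draw_gaussian_natural(P, as.numeric(b))
}

#' One Gibbs update of the between-person level
#'
#' Updates, in turn: the latent ADHD and internalising factor scores (normal
#' full conditionals combining measurement and structural information), the
#' ADHD factor variance, all measurement parameters (intercepts, free
#' loadings, the cross-loading, item residual variances; reference loadings
#' stay fixed at 1), the regressions of the six random effects on ADHD (and
#' covariates), and the structural equation of internalising. All updates are
#' conjugate: normal for locations, inverse-gamma for variances.
#'
#' @param re N x 6 matrix of current person random effects (columns named as
#'   in [true_model()]).
#' @param items_adhd,items_int numeric matrices of trait item responses.
#' @param covs N x k covariate matrix or NULL (baseline model).
#' @param params current parameter list (see [run_mcmc()] internals).
#' @param cross_idx column index of the cross-loading item in `items_adhd`.
#' @param center fixed 6-vector subtracted from the random effects wherever
#'   they predict internalising; data-derived constants that keep the
#'   factor's location near zero (the structural intercept is fixed at 0
#'   for identification).
#' @param priors list with `loc_prec` (prior precision of intercepts),
#'   `slope_prec` (prior precision of loadings and regression slopes; the
#'   default 0.04 is a weakly informative Normal(0, 25) that keeps the
#'   factor-scale parameters proper), `ig_a`, `ig_b` (variance prior;
#'   defaults give the uniform-on-SD prior).
#' @return The updated parameter list.
#' @export
sample_between <- function(re, items_adhd, items_int, covs, params,
                           cross_idx = 5L, center = rep(0, 6),
                           priors = list(loc_prec = 1e-6, slope_prec = 0.04,
                                         ig_a = -0.5, ig_b = 0)) {
  n <- nrow(re)
  p <- params
  has_cov <- !is.null(covs)
  rec <- sweep(re, 2, center)
  cov_term_re <- if (has_cov) covs %*% t(p$gamma_cov) else matrix(0, n, 6)
  cov_term_eta <- if (has_cov) as.numeric(covs %*% p$beta_cov) else 0

  # ---- latent ADHD factor scores ----
  prec <- rep(1 / p$psi_adhd, n)
  b <- rep(0, n)
  for (j in seq_len(ncol(items_adhd))) {
    resid <- items_adhd[, j] - p$alpha_adhd[j]
    if (j == cross_idx) resid <- resid - p$lambda_cross * p$eta
    prec <- prec + p$lambda_adhd[j]^2 / p$theta_adhd[j]
    b <- b + p$lambda_adhd[j] * resid / p$theta_adhd[j]
  }
  for (k in 1:6) {
    g <- p$gamma_adhd[k]
    prec <- prec + g^2 / p$tau2[k]
    b <- b + g * (re[, k] - p$nu[k] - cov_term_re[, k]) / p$tau2[k]
  }
  prec <- prec + p$beta_adhd^2 / p$sigma_int2
  b <- b + p$beta_adhd *
    (p$eta - p$beta0 - as.numeric(rec %*% p$beta_int) - cov_term_eta) /
    p$sigma_int2
  p$adhd <- rnorm(n, b / prec, sqrt(1 / prec))

  # ---- latent internalising factor scores ----
  struct_mean <- p$beta0 + as.numeric(rec %*% p$beta_int) +
    p$beta_adhd * p$adhd + cov_term_eta
  prec <- rep(1 / p$sigma_int2, n)
  b <- struct_mean / p$sigma_int2
  for (j in seq_len(ncol(items_int))) {
    prec <- prec + p$lambda_int[j]^2 / p$theta_int[j]
    b <- b + p$lambda_int[j] * (items_int[, j] - p$alpha_int[j]) / p$theta_int[j]
  }
  resid <- items_adhd[, cross_idx] - p$alpha_adhd[cross_idx] -
    p$lambda_adhd[cross_idx] * p$adhd
  prec <- prec + p$lambda_cross^2 / p$theta_adhd[cross_idx]
  b <- b + p$lambda_cross * resid / p$theta_adhd[cross_idx]
  p$eta <- rnorm(n, b / prec, sqrt(1 / prec))

  # ---- ADHD factor variance ----
  p$psi_adhd <- rinvgamma1(priors$ig_a + n / 2,
                           priors$ig_b + sum(p$adhd^2) / 2)

  # ---- measurement parameters ----
  for (j in seq_len(ncol(items_adhd))) {
    yj <- items_adhd[, j]
    if (j == 1L) {                       # reference: loading fixed at 1
      X <- matrix(1, n, 1)
      yy <- yj - p$adhd
      if (j == cross_idx) yy <- yy - p$lambda_cross * p$eta
      cf <- draw_reg(X, yy, p$theta_adhd[j], priors$loc_prec)
      p$alpha_adhd[j] <- cf[1]
      fitted <- cf[1] + p$adhd + if (j == cross_idx) p$lambda_cross * p$eta else 0
    } else if (j == cross_idx) {
      X <- cbind(1, p$adhd, p$eta)
      cf <- draw_reg(X, yj, p$theta_adhd[j],
                     c(priors$loc_prec, priors$slope_prec, priors$slope_prec))
      p$alpha_adhd[j] <- cf[1]; p$lambda_adhd[j] <- cf[2]; p$lambda_cross <- cf[3]
      fitted <- as.numeric(X %*% cf)
    } else {
      X <- cbind(1, p$adhd)
      cf <- draw_reg(X, yj, p$theta_adhd[j],
                     c(priors$loc_prec, priors$slope_prec))
      p$alpha_adhd[j] <- cf[1]; p$lambda_adhd[j] <- cf[2]
      fitted <- as.numeric(X %*% cf)
    }
    p$theta_adhd[j] <- rinvgamma1(priors$ig_a + n / 2,
                                  priors$ig_b + sum((yj - fitted)^2) / 2)
  }
  for (j in seq_len(ncol(items_int))) {
    yj <- items_int[, j]
    if (j == 1L) {
      cf <- draw_reg(matrix(1, n, 1), yj - p$eta, p$theta_int[j],
                     priors$loc_prec)
      p$alpha_int[j] <- cf[1]
      fitted <- cf[1] + p$eta
    } else {
      X <- cbind(1, p$eta)
      cf <- draw_reg(X, yj, p$theta_int[j],
                     c(priors$loc_prec, priors$slope_prec))
      p$alpha_int[j] <- cf[1]; p$lambda_int[j] <- cf[2]
      fitted <- as.numeric(X %*% cf)
    }
    p$theta_int[j] <- rinvgamma1(priors$ig_a + n / 2,
                                 priors$ig_b + sum((yj - fitted)^2) / 2)
  }

  # ---- random effects regressed on ADHD (and covariates) ----
  X <- if (has_cov) cbind(1, p$adhd, covs) else cbind(1, p$adhd)
  for (k in 1:6) {
    cf <- draw_reg(X, re[, k], p$tau2[k],
                   c(priors$loc_prec, rep(priors$slope_prec, ncol(X) - 1)))
    p$nu[k] <- cf[1]; p$gamma_adhd[k] <- cf[2]
    if (has_cov) p$gamma_cov[k, ] <- cf[-(1:2)]
    ssr <- sum((re[, k] - as.numeric(X %*% cf))^2)
    p$tau2[k] <- rinvgamma1(priors$ig_a + n / 2, priors$ig_b + ssr / 2)
  }

  # ---- internalising structural equation ----
  # no free intercept: the factor location is identified through the item
  # intercepts, so the structural intercept is fixed at zero
  X <- if (has_cov) cbind(rec, p$adhd, covs) else cbind(rec, p$adhd)
  cf <- draw_reg(X, p$eta, p$sigma_int2, priors$slope_prec)
  p$beta0 <- 0; p$beta_int <- cf[1:6]; p$beta_adhd <- cf[7]
  if (has_cov) p$beta_cov <- cf[-(1:7)]
  ssr <- sum((p$eta - as.numeric(X %*% cf))^2)
  p$sigma_int2 <- rinvgamma1(priors$ig_a + n / 2, priors$ig_b + ssr / 2)

  # scale moves along the factor-identification ridges
  p <- scale_move_adhd(p, items_adhd, cross_idx, priors)
  p <- scale_move_eta(p, items_int, has_cov, priors)

  p
}

# ---- latent-scale group moves -------------------------------------------
#
# The posterior of a reference-indicator-identified factor model has a long
# ridge along which the factor scale trades off against every loading and
# slope attached to the factor; single-site Gibbs crawls along it. These
# Metropolis moves propose a coordinated rescaling (factor scores and factor
# variance up, attached coefficients down), which leaves every likelihood
# term invariant except the reference indicator's, and correct for priors
# and the Jacobian of the transformation. They leave the posterior invariant
# and cut the autocorrelation time of the scale parameters by orders of
# magnitude.

ig_logd <- function(x, a, b) -(a + 1) * log(x) - b / x

# Rescale the ADHD factor: A -> cA, psi -> c^2 psi, free ADHD loadings,
# gamma and beta_adhd divided by c.
scale_move_adhd <- function(p, items_adhd, cross_idx, priors, steps = 2) {
  n <- length(p$adhd)
  y1 <- items_adhd[, 1]
  for (s in seq_len(steps)) {
    lc <- rnorm(1, 0, 0.15)
    c_ <- exp(lc)
    r_old <- y1 - p$alpha_adhd[1] - p$adhd
    r_new <- y1 - p$alpha_adhd[1] - c_ * p$adhd
    d_ll <- -(sum(r_new^2) - sum(r_old^2)) / (2 * p$theta_adhd[1])
    scaled <- c(p$lambda_adhd[-1], p$gamma_adhd, p$beta_adhd)
    d_prior <- ig_logd(c_^2 * p$psi_adhd, priors$ig_a, priors$ig_b) -
      ig_logd(p$psi_adhd, priors$ig_a, priors$ig_b) -
      priors$slope_prec / 2 * (sum((scaled / c_)^2) - sum(scaled^2))
    # the c^N Jacobian of rescaling the N factor scores cancels against
    # the c^-N ratio of their N(0, psi) prior; what remains is psi's own
    # Jacobian and the divided coefficients
    log_jac <- (2 - length(scaled)) * lc
    if (log(runif(1)) < d_ll + d_prior + log_jac) {
      p$adhd <- c_ * p$adhd
      p$psi_adhd <- c_^2 * p$psi_adhd
      p$lambda_adhd[-1] <- p$lambda_adhd[-1] / c_
      p$gamma_adhd <- p$gamma_adhd / c_
      p$beta_adhd <- p$beta_adhd / c_
    }
  }
  p
}

# Rescale the internalising factor: eta -> c eta, its free loadings and the
# cross-loading divided by c, the structural coefficients and residual
# variance scaled up to keep the structural equation invariant.
scale_move_eta <- function(p, items_int, has_cov, priors, steps = 2) {
  n <- length(p$eta)
  y1 <- items_int[, 1]
  n_cov <- if (has_cov) length(p$beta_cov) else 0
  for (s in seq_len(steps)) {
    lc <- rnorm(1, 0, 0.15)
    c_ <- exp(lc)
    r_old <- y1 - p$alpha_int[1] - p$eta
    r_new <- y1 - p$alpha_int[1] - c_ * p$eta
    d_ll <- -(sum(r_new^2) - sum(r_old^2)) / (2 * p$theta_int[1])
    down <- c(p$lambda_int[-1], p$lambda_cross)         # divided by c
    up <- c(p$beta_int, p$beta_adhd, if (has_cov) p$beta_cov)  # times c
    d_prior <- ig_logd(c_^2 * p$sigma_int2, priors$ig_a, priors$ig_b) -
      ig_logd(p$sigma_int2, priors$ig_a, priors$ig_b) -
      priors$slope_prec / 2 * (sum((down / c_)^2) - sum(down^2)) -
      priors$slope_prec / 2 * (sum((up * c_)^2) - sum(up^2))
    # as above: the factor-score Jacobian cancels against the structural
    # density ratio
    log_jac <- (2 - length(down) + length(up)) * lc
    if (log(runif(1)) < d_ll + d_prior + log_jac) {
      p$eta <- c_ * p$eta
      p$sigma_int2 <- c_^2 * p$sigma_int2
      p$lambda_int[-1] <- p$lambda_int[-1] / c_
      p$lambda_cross <- p$lambda_cross / c_
      p$beta_int <- c_ * p$beta_int
      p$beta_adhd <- c_ * p$beta_adhd
      if (has_cov) p$beta_cov <- c_ * p$beta_cov
    }
  }
  p
}

# Vectorised within-person log-likelihood (up to a constant) for all persons
# at arbitrary (mu, theta), from the raw per-person sufficient statistics
# returned by the compiled sweep. Columns of `ps`: L11 L12 L22 C11 C12 C21
# C22 U11 U12 U22 sl1 sl2 su1 su2 ntr.
within_ll_vec <- function(mu, theta, W, ps) {
  m1 <- mu[, 1]; m2 <- mu[, 2]
  a <- theta[, 1]; b <- theta[, 2]; cc <- theta[, 3]; d <- theta[, 4]
  n <- ps[, 15]
  sxx11 <- ps[, 1] - 2 * ps[, 11] * m1 + n * m1^2
  sxx12 <- ps[, 2] - ps[, 11] * m2 - ps[, 12] * m1 + n * m1 * m2
  sxx22 <- ps[, 3] - 2 * ps[, 12] * m2 + n * m2^2
  sxy11 <- ps[, 4] - m1 * ps[, 13] - m1 * ps[, 11] + n * m1 * m1
  sxy12 <- ps[, 5] - m2 * ps[, 11] - m1 * ps[, 14] + n * m1 * m2
  sxy21 <- ps[, 6] - m1 * ps[, 12] - m2 * ps[, 13] + n * m1 * m2
  sxy22 <- ps[, 7] - m2 * ps[, 12] - m2 * ps[, 14] + n * m2 * m2
  syy11 <- ps[, 8] - 2 * ps[, 13] * m1 + n * m1^2
  syy12 <- ps[, 9] - ps[, 13] * m2 - ps[, 14] * m1 + n * m1 * m2
  syy22 <- ps[, 10] - 2 * ps[, 14] * m2 + n * m2^2
  w11 <- W[1, 1]; w12 <- W[1, 2]; w22 <- W[2, 2]
  p11 <- a * sxy11 + b * sxy21; p12 <- a * sxy12 + b * sxy22
  p21 <- cc * sxy11 + d * sxy21; p22 <- cc * sxy12 + d * sxy22
  tr1 <- w11 * p11 + w12 * (p12 + p21) + w22 * p22
  m11 <- a^2 * sxx11 + 2 * a * b * sxx12 + b^2 * sxx22
  m12 <- a * cc * sxx11 + (a * d + b * cc) * sxx12 + b * d * sxx22
  m22 <- cc^2 * sxx11 + 2 * cc * d * sxx12 + d^2 * sxx22
  tr2 <- w11 * m11 + 2 * w12 * m12 + w22 * m22
  tr0 <- w11 * syy11 + 2 * w12 * syy12 + w22 * syy22
  -0.5 * (tr0 - 2 * tr1 + tr2)
}

# Interweaving scale moves for the six random-effect scales: jointly rescale
# every person's deviation from the conditional prior mean together with the
# residual SD of that random effect. This is the non-centered counterpart of
# the centered Gibbs updates and breaks the critical slowing between tau^2
# and the person effects when per-person information is weak.
re_scale_moves <- function(mu, theta, tau2, pstats, pr_mean, params, covs,
                           sigma_w, priors, center = rep(0, 6),
                           step = 0.25, sweeps = 2) {
  rn <- re_names()
  W <- solve(sigma_w)
  n <- nrow(mu)
  p <- params
  cov_term_eta <- if (!is.null(covs)) as.numeric(covs %*% p$beta_cov) else 0
  re_of <- function(mu, theta) cbind(mu, theta[, c(1, 4, 2, 3), drop = FALSE])
  ll_cur <- sum(within_ll_vec(mu, theta, W, pstats))
  e_cur <- p$eta - p$beta0 -
    as.numeric(sweep(re_of(mu, theta), 2, center) %*% p$beta_int) -
    p$beta_adhd * p$adhd - cov_term_eta
  for (k in rep(seq_along(rn), sweeps)) {
    lc <- rnorm(1, 0, step)
    c_ <- exp(lc)
    v <- re_of(mu, theta)[, k]
    v_new <- pr_mean[, k] + c_ * (v - pr_mean[, k])
    mu_new <- mu; theta_new <- theta
    if (k <= 2) mu_new[, k] <- v_new
    else {
      th_col <- match(rn[k], th_names())
      theta_new[, th_col] <- v_new
    }
    ll_new <- sum(within_ll_vec(mu_new, theta_new, W, pstats))
    e_new <- e_cur - p$beta_int[k] * (v_new - v)
    d_eta <- -(sum(e_new^2) - sum(e_cur^2)) / (2 * p$sigma_int2)
    d_prior <- ig_logd(c_^2 * tau2[k], priors$ig_a, priors$ig_b) -
      ig_logd(tau2[k], priors$ig_a, priors$ig_b)
    if (is.finite(ll_new) &&
        log(runif(1)) < ll_new - ll_cur + d_eta + d_prior + 2 * lc) {
      mu <- mu_new; theta <- theta_new
      tau2[k] <- c_^2 * tau2[k]
      ll_cur <- ll_new
      e_cur <- e_new
    }
  }
  list(mu = mu, theta = theta, tau2 = tau2)
}

#' Potential scale reduction diagnostic
#'
#' Gelman-Rubin statistic comparing within- and between-chain variance:
#' `sqrt(((n - 1) / n * W + B / n) / W)` per parameter, where `W` is the mean
#' within-chain variance and `B / n` the variance of the chain means.
#'
#' @param draws a list of chain matrices (iterations x parameters, identical
#'   column names) or a 3-d array `iterations x chains x parameters`.
#' @return Named vector of PSR values, floored at 1 (identical chains give
#'   exactly 1). Parameters whose within-chain variance is zero are
#'   flagged in the `degenerate` attribute; their PSR is 1 when the chains
#'   agree exactly and `Inf` otherwise.
#' @export
psr <- function(draws) {
  if (is.array(draws) && length(dim(draws)) == 3) {
    draws <- lapply(seq_len(dim(draws)[2]), function(c) draws[, c, ])
  }
  stopifnot(length(draws) >= 2)
  n <- nrow(draws[[1]])
  stopifnot(n >= 10)
  params <- colnames(draws[[1]]) %||% paste0("p", seq_len(ncol(draws[[1]])))
  W <- Reduce(`+`, lapply(draws, function(d) apply(d, 2, var))) / length(draws)
  means <- do.call(rbind, lapply(draws, colMeans))
  B_over_n <- apply(means, 2, var)
  r <- sqrt(((n - 1) / n * W + B_over_n) / W)
  r <- pmax(r, 1)                 # the (n-1)/n deflation is never evidence
  r[W == 0 & B_over_n == 0] <- 1
  r[W == 0 & B_over_n > 0] <- Inf
  names(r) <- params
  attr(r, "degenerate") <- params[W == 0]
  r
}
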