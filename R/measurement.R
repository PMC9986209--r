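# Questionnaire measurement: sum scoring, a two-factor confirmatory factor
# model (ADHD + internalising, one cross-loading) fitted by normal-theory
# maximum likelihood with items treated as continuous, fit indices and
# McDonald's omega. Missing item responses are handled by full-information
# ML over the observed-data likelihood, grouped by missingness pattern.

#' Sum-score questionnaire scales
#'
#' @param items tibble/data.frame of item responses on a 1-5 scale.
#' @param scales named list mapping scale name to item column names.
#' @param min_score,max_score admissible item range.
#' @return A tibble with one sum-score column per scale; a score is missing if
#'   any constituent item is missing (no proration).
#' @export
score_scales <- function(items, scales, min_score = 1, max_score = 5) {
  items <- as_tibble(items)
  out <- purrr::map(scales, function(cols) {
    m <- as.matrix(items[, cols])
    if (any(m < min_score | m > max_score, na.rm = TRUE)) {
      abort("Item response outside the admissible range.")
    }
    s <- rowSums(m)                       # NA if any item missing
    s
  })
  as_tibble(out)
}

#' Specify a confirmatory factor model
#'
#' @param factors named list: factor name -> character vector of item names.
#'   The first item of each factor is its reference indicator (loading fixed
#'   at 1).
#' @param cross named list of extra loadings: item name -> factor name.
#' @return A `cfa_spec` object.
#' @export
cfa_spec <- function(factors, cross = list()) {
  stopifnot(length(factors) >= 1, !is.null(names(factors)))
  structure(list(factors = factors, cross = cross), class = "cfa_spec")
}

# Default two-factor trait model: 9 ADHD + 14 internalising items, with the
# restless-inside ADHD item cross-loading on internalising.
default_trait_spec <- function(cross_item = "adhd5") {
  cfa_spec(
    factors = list(adhd = paste0("adhd", 1:9),
                   internalising = paste0("int", 1:14)),
    cross = stats::setNames(list("internalising"), cross_item))
}

# Build the loading pattern matrix skeleton: 1 = free, entries for reference
# indicators fixed at 1.
cfa_pattern <- function(spec, item_names) {
  nf <- length(spec$factors)
  p <- length(item_names)
  lam_free <- matrix(FALSE, p, nf, dimnames = list(item_names, names(spec$factors)))
  lam_fix <- matrix(0, p, nf, dimnames = dimnames(lam_free))
  for (f in seq_len(nf)) {
    its <- spec$factors[[f]]
    stopifnot(all(its %in% item_names))
    lam_fix[its[1], f] <- 1
    lam_free[its[-1], f] <- TRUE
  }
  for (it in names(spec$cross)) {
    lam_free[it, spec$cross[[it]]] <- TRUE
  }
  list(free = lam_free, fixed = lam_fix)
}

cfa_unpack <- function(theta, pat, p, nf) {
  lam <- pat$fixed
  lam[pat$free] <- theta[seq_len(sum(pat$free))]
  k <- sum(pat$free)
  # factor covariance via log-Cholesky
  L <- matrix(0, nf, nf)
  diag(L) <- exp(theta[k + seq_len(nf)])
  if (nf > 1) L[lower.tri(L)] <- theta[k + nf + seq_len(nf * (nf - 1) / 2)]
  psi <- L %*% t(L)
  k2 <- k + nf + nf * (nf - 1) / 2
  thetad <- exp(theta[k2 + seq_len(p)])
  nu <- theta[k2 + p + seq_len(p)]
  list(lambda = lam, psi = psi, theta = thetad, nu = nu)
}

cfa_sigma <- function(par) {
  par$lambda %*% par$psi %*% t(par$lambda) + diag(par$theta)
}

# -2 log-likelihood, pattern-grouped FIML (multivariate normal).
cfa_m2ll <- function(theta, pat, y, patterns) {
  p <- ncol(y); nf <- ncol(pat$fixed)
  par <- cfa_unpack(theta, pat, p, nf)
  sigma <- cfa_sigma(par)
  m2ll <- 0
  for (g in patterns) {
    obs <- g$obs
    S <- sigma[obs, obs, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(1e12)
    yc <- sweep(g$y, 2, par$nu[obs], `-`)
    z <- yc %*% backsolve(ch, diag(length(obs)))
    m2ll <- m2ll + nrow(g$y) * (length(obs) * log(2 * pi) +
                                  2 * sum(log(diag(ch)))) + sum(z^2)
  }
  m2ll
}

split_patterns <- function(y) {
  key <- apply(!is.na(y), 1, paste, collapse = "")
  lapply(split(seq_len(nrow(y)), key), function(idx) {
    obs <- which(!is.na(y[idx[1], ]))
    list(obs = obs, y = y[idx, obs, drop = FALSE])
  })
}

# -2 logL of the saturated and independence models (FIML).
saturated_m2ll <- function(y, diagonal = FALSE) {
  patterns <- split_patterns(y)
  p <- ncol(y)
  n <- nrow(y)
  mu <- colMeans(y, na.rm = TRUE)
  if (diagonal) {
    sig <- diag(apply(y, 2, function(col) mean((col - mean(col, na.rm = TRUE))^2,
                                               na.rm = TRUE)), p)
    m2ll_eval(mu, sig, patterns)
  } else if (!anyNA(y)) {
    S <- cov(y) * (n - 1) / n
    m2ll_eval(mu, S, patterns)
  } else {
    # EM for the unstructured mean/covariance under missingness
    S <- cov(y, use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
    diag(S)[diag(S) <= 0] <- 1
    for (iter in 1:200) {
      res <- em_step_mvn(y, mu, S, patterns)
      if (max(abs(res$mu - mu)) < 1e-8 && max(abs(res$S - S)) < 1e-8) break
      mu <- res$mu; S <- res$S
    }
    m2ll_eval(mu, S, patterns)
  }
}

m2ll_eval <- function(mu, sigma, patterns) {
  m2ll <- 0
  for (g in patterns) {
    obs <- g$obs
    ch <- chol(sigma[obs, obs, drop = FALSE])
    yc <- sweep(g$y, 2, mu[obs], `-`)
    z <- yc %*% backsolve(ch, diag(length(obs)))
    m2ll <- m2ll + nrow(g$y) * (length(obs) * log(2 * pi) +
                                  2 * sum(log(diag(ch)))) + sum(z^2)
  }
  m2ll
}

em_step_mvn <- function(y, mu, S, patterns) {
  n <- nrow(y); p <- ncol(y)
  sum1 <- rep(0, p); sum2 <- matrix(0, p, p)
  for (g in patterns) {
    obs <- g$obs; mis <- setdiff(seq_len(p), obs)
    ng <- nrow(g$y)
    yy <- matrix(NA_real_, ng, p)
    yy[, obs] <- g$y
    cvar <- matrix(0, p, p)
    if (length(mis) > 0) {
      Soo <- S[obs, obs, drop = FALSE]
      B <- S[mis, obs, drop = FALSE] %*% solve(Soo)
      yy[, mis] <- matrix(mu[mis], ng, length(mis), byrow = TRUE) +
        sweep(g$y, 2, mu[obs], `-`) %*% t(B)
      cvar[mis, mis] <- (S[mis, mis, drop = FALSE] -
                           B %*% S[obs, mis, drop = FALSE]) * ng
    }
    sum1 <- sum1 + colSums(yy)
    sum2 <- sum2 + crossprod(yy) + cvar
  }
  mu_new <- sum1 / n
  list(mu = mu_new, S = sum2 / n - tcrossprod(mu_new))
}

#' Fit indices from model and baseline chi-square statistics
#'
#' Computes CFI, TLI, RMSEA and the information criteria from the likelihood
#' ratio statistics of the fitted and the baseline (independence) model:
#' `CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, 0)`.
#'
#' @param chi2_m,df_m fitted-model chi-square and degrees of freedom.
#' @param chi2_b,df_b baseline-model chi-square and degrees of freedom.
#' @param n sample size.
#' @param srmr optional standardised root mean square residual to carry along.
#' @param m2ll optional -2 log-likelihood and `k` free-parameter count for BIC.
#' @param k number of free parameters.
#' @return A tibble with one row of fit indices.
#' @export
fit_indices <- function(chi2_m, df_m, chi2_b, df_b, n, srmr = NA_real_,
                        m2ll = NA_real_, k = NA_real_) {
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df_m == 0 || df_b == 0) 1 else {
    min((chi2_b / df_b - chi2_m / df_m) / (chi2_b / df_b - 1), 1)
  }
  rmsea <- if (df_m == 0) 0 else sqrt(max(chi2_m - df_m, 0) / (df_m * n))
  tibble(chi2 = chi2_m, df = df_m, chi2_baseline = chi2_b,
         df_baseline = df_b, cfi = cfi, tli = tli, rmsea = rmsea,
         srmr = srmr, bic = m2ll + k * log(n), n = n, k = k)
}

#' Fit a confirmatory factor model
#'
#' Normal-theory ML treating the 1-5 items as continuous, with
#' full-information ML over the casewise observed-data likelihood when item
#' responses are missing. Reference loadings are fixed at 1; factor
#' covariances are free.
#'
#' @param items tibble/data.frame of item responses (persons x items).
#' @param spec a [cfa_spec()]; defaults to the two-factor ADHD/internalising
#'   model with the restless-inside cross-loading.
#' @param se compute standard errors from the numerically differentiated
#'   observed information (default TRUE).
#' @return A `cfa_fit` object with loadings, factor covariance, residual
#'   variances, intercepts, fit indices, convergence status and Heywood flag.
#' @export
fit_cfa <- function(items, spec = default_trait_spec(), se = TRUE) {
  y <- as.matrix(as_tibble(items)[, unlist(spec$factors), drop = FALSE])
  storage.mode(y) <- "double"
  item_names <- colnames(y)
  p <- ncol(y); nf <- length(spec$factors); n <- nrow(y)
  pat <- cfa_pattern(spec, item_names)
  n_free_load <- sum(pat$free)
  k <- n_free_load + nf + nf * (nf - 1) / 2 + p + p   # + p intercepts
  if (n <= k) abort("More free parameters than persons.")
  patterns <- split_patterns(y)

  sdy <- apply(y, 2, sd, na.rm = TRUE)
  start <- c(rep(0.8, n_free_load),                 # free loadings
             rep(log(stats::median(sdy) * 0.7), nf),# log chol diag
             rep(0, nf * (nf - 1) / 2),
             log(pmax(sdy^2 / 2, 1e-3)),            # log residual variances
             colMeans(y, na.rm = TRUE))             # intercepts
  obj <- function(th) cfa_m2ll(th, pat, y, patterns)
  opt <- nlminb(start, obj, control = list(iter.max = 2000, eval.max = 4000))
  par <- cfa_unpack(opt$par, pat, p, nf)
  dimnames(par$psi) <- list(names(spec$factors), names(spec$factors))
  converged <- opt$convergence == 0

  # chi-square against the saturated model; baseline = independence model.
  m2ll_sat <- saturated_m2ll(y)
  m2ll_base <- saturated_m2ll(y, diagonal = TRUE)
  chi2_m <- max(opt$objective - m2ll_sat, 0)
  df_m <- p * (p + 1) / 2 - (k - p)                  # means saturated
  chi2_b <- max(m2ll_base - m2ll_sat, 0)
  df_b <- p * (p + 1) / 2 - p

  sigma_hat <- cfa_sigma(par)
  if (!anyNA(y)) {
    S <- cov(y) * (n - 1) / n
    d <- sqrt(diag(S))
    res <- (S - sigma_hat) / tcrossprod(d)
    srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  } else srmr <- NA_real_

  fit <- fit_indices(chi2_m, df_m, chi2_b, df_b, n, srmr = srmr,
                     m2ll = opt$objective, k = k)

  se_tab <- NULL
  if (se) {
    H <- tryCatch(optimHess(opt$par, obj), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H / 2), error = function(e) NULL)  # H of -2logL
      if (!is.null(V)) {
        se_all <- sqrt(pmax(diag(V), 0))
        se_lam <- matrix(NA_real_, p, nf, dimnames = dimnames(pat$fixed))
        se_lam[pat$free] <- se_all[seq_len(n_free_load)]
        se_tab <- se_lam
      }
    }
  }

  structure(list(
    spec = spec, lambda = par$lambda, psi = par$psi,
    theta = stats::setNames(par$theta, item_names),
    nu = stats::setNames(par$nu, item_names),
    lambda_se = se_tab, fit = fit, converged = converged,
    heywood = any(par$theta < 1e-4), n = n, m2ll = opt$objective, k = k),
    class = "cfa_fit")
}

#' McDonald's omega reliability
#'
#' `omega = (sum lambda)^2 psi_ff / ((sum lambda)^2 psi_ff + sum theta)` over
#' the items whose primary loading is on `factor`. Including the factor
#' variance makes omega invariant to which indicator serves as the reference.
#'
#' @param fit a `cfa_fit` (or a list with `lambda`, `psi`, `theta`, `spec`).
#' @param factor factor name.
#' @return Reliability in (0, 1).
#' @export
omega <- function(fit, factor) {
  its <- fit$spec$factors[[factor]]
  lam <- fit$lambda[its, factor]
  th <- fit$theta[its]
  num <- sum(lam)^2 * fit$psi[factor, factor]
  num / (num + sum(th))
}

#' Compare the BIC of two fitted measurement models
#'
#' @param fit1,fit2 `cfa_fit` objects on the same data.
#' @return BIC(fit1) - BIC(fit2); negative favours `fit1`.
#' @export
delta_bic <- function(fit1, fit2) {
  (fit1$m2ll + fit1$k * log(fit1$n)) - (fit2$m2ll + fit2$k * log(fit2$n))
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat("<cfa_fit>", length(x$spec$factors), "factors,", nrow(x$lambda),
      "items, n =", x$n, if (!x$converged) "(NOT CONVERGED)", "\n")
  print(x$fit[, c("chi2", "df", "cfi", "tli", "rmsea", "srmr")])
  invisible(x)
}

#' @rdname fit_cfa
#' @param x a `cfa_fit`.
#' @param ... unused.
#' @export
tidy.cfa_fit <- function(x, ...) {
  nf <- names(x$spec$factors)
  purrr::map_dfr(nf, function(f) {
    idx <- which(x$lambda[, f] != 0)
    tibble(factor = f, item = rownames(x$lambda)[idx],
           loading = x$lambda[idx, f],
           se = if (is.null(x$lambda_se)) NA_real_ else x$lambda_se[idx, f],
           reference = rownames(x$lambda)[idx] == x$spec$factors[[f]][1])
  })
}

#' @rdname fit_cfa
#' @export
glance.cfa_fit <- function(x, ...) {
  dplyr::mutate(x$fit, converged = x$converged, heywood = x$heywood)
}
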