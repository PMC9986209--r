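# Gibbs sampler driver: chain initialisation, blockwise advancement with
# periodic convergence checks, iteration doubling after first convergence,
# thinning and burn-in.

# theta (transition-coefficient) column order and its position in the
# random-effect vector (mu_s, mu_a, phi_ss, phi_aa, phi_as, phi_sa).
th_names <- function() c("phi_ss", "phi_as", "phi_sa", "phi_aa")
th_in_re <- function() c(3L, 5L, 6L, 4L)

#' MCMC configuration
#'
#' @param n_chains number of independent chains (>= 2 for the PSR check).
#' @param max_iterations hard cap on iterations per chain.
#' @param min_iterations minimum iterations per chain before convergence
#'   stopping applies.
#' @param thinning record every `thinning`-th iteration.
#' @param psr_threshold convergence threshold for the potential scale
#'   reduction of every monitored parameter.
#' @param burn_in_fraction fraction of each chain discarded before
#'   summarising (and before the final PSR computation).
#' @param check_every iterations between convergence checks; rounded to a
#'   multiple of `thinning`.
#' @param double_on_first_convergence once all PSR values first fall below
#'   the threshold, double the completed iteration count before stopping.
#' @param jitter_sd SD of the overdispersed chain-specific jitter added to
#'   population location starting values.
#' @param seed integer seed; chain seeds are derived from it.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 2, max_iterations = 50000,
                        min_iterations = 0, thinning = 10,
                        psr_threshold = 1.05, burn_in_fraction = 0.5,
                        check_every = 1000,
                        double_on_first_convergence = TRUE,
                        jitter_sd = 0.5, seed = 1) {
  stopifnot(thinning >= 1, n_chains >= 1, max_iterations >= thinning,
            burn_in_fraction > 0, burn_in_fraction < 1)
  check_every <- max(thinning, round(check_every / thinning) * thinning)
  structure(list(n_chains = as.integer(n_chains),
                 max_iterations = as.integer(max_iterations),
                 min_iterations = as.integer(min_iterations),
                 thinning = as.integer(thinning),
                 psr_threshold = psr_threshold,
                 burn_in_fraction = burn_in_fraction,
                 check_every = as.integer(check_every),
                 double_on_first_convergence = double_on_first_convergence,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "mcmc_config")
}

# Reshape an aligned_ema tibble into the arrays the sampler consumes.
prepare_series <- function(aligned) {
  ids <- unique(aligned$person_id)
  n <- length(ids)
  t_max <- max(tapply(aligned$slot, aligned$person_id, max)) + 1L
  Y <- array(0, c(t_max, 2, n))
  obs1 <- matrix(0L, t_max, n)
  obs2 <- matrix(0L, t_max, n)
  first <- integer(n); last <- integer(n)
  for (i in seq_len(n)) {
    d <- aligned[aligned$person_id == ids[i], ]
    sl <- d$slot + 1L
    Y[sl, 1, i] <- ifelse(is.na(d$stress), 0, d$stress)
    Y[sl, 2, i] <- ifelse(is.na(d$affect), 0, d$affect)
    obs1[sl, i] <- as.integer(!is.na(d$stress))
    obs2[sl, i] <- as.integer(!is.na(d$affect))
    full <- which(obs1[, i] == 1 & obs2[, i] == 1)
    if (length(full) == 0) abort("A person has no fully observed slot.")
    first[i] <- min(full) - 1L
    last[i] <- max(full) - 1L
  }
  list(ids = ids, Y = Y, obs1 = obs1, obs2 = obs2, first = first, last = last,
       n = n, t_max = t_max)
}

init_chain <- function(dat, items_adhd, items_int, covs, model, cfg,
                       re_prior, chain_seed, init_values = NULL) {
  set.seed(chain_seed)
  n <- dat$n
  jit <- function(k, s = cfg$jitter_sd) rnorm(k, 0, s)

  mu <- matrix(0, n, 2)
  theta <- matrix(0, n, 4)
  Y <- dat$Y
  for (i in seq_len(n)) {
    o1 <- dat$obs1[, i] == 1; o2 <- dat$obs2[, i] == 1
    mu[i, 1] <- mean(Y[o1, 1, i]); mu[i, 2] <- mean(Y[o2, 2, i])
    # fill missing cells with the person mean
    Y[!o1, 1, i] <- mu[i, 1]; Y[!o2, 2, i] <- mu[i, 2]
    # per-person least-squares start for the transition coefficients
    rng <- (dat$first[i] + 1):(dat$last[i] + 1)
    if (length(rng) >= 6) {
      x <- sweep(Y[rng, , i], 2, mu[i, ])
      xl <- x[-nrow(x), , drop = FALSE]; xr <- x[-1, , drop = FALSE]
      sxx <- crossprod(xl)
      if (all(is.finite(sxx)) && det(sxx) > 1e-8) {
        B <- solve(sxx, crossprod(xl, xr))     # 2x2, columns = outcomes
        if (all(abs(B) < 1.5)) {
          theta[i, ] <- c(B[1, 1], B[2, 1], B[1, 2], B[2, 2])
        }
      }
    }
  }

  # within-person residual scale for the innovation covariance start
  dev_var <- c(0, 0)
  for (j in 1:2) {
    obs <- if (j == 1) dat$obs1 else dat$obs2
    devs <- unlist(lapply(seq_len(n), function(i) {
      Y[obs[, i] == 1, j, i] - mu[i, j]
    }))
    dev_var[j] <- max(var(devs), 0.1)
  }
  sigma_w <- diag(dev_var * 0.8)

  params <- NULL
  if (model != "none") {
    rn <- re_names()
    re0 <- cbind(mu, theta[, c(1, 4, 2, 3), drop = FALSE])
    colnames(re0) <- rn
    zrow <- function(m) {
      z <- rowMeans(scale(m))
      z[!is.finite(z)] <- 0
      as.numeric(scale(z))
    }
    params <- list(
      nu = colMeans(re0) + jit(6) * c(1, 1, .1, .1, .1, .1),
      gamma_adhd = jit(6, 0.1),
      gamma_cov = if (!is.null(covs))
        matrix(jit(6 * ncol(covs), 0.1), 6, ncol(covs)) else NULL,
      tau2 = pmax(apply(re0, 2, var), c(.1, .1, .005, .005, .005, .005)),
      psi_adhd = 1,
      beta0 = 0, beta_int = jit(6, 0.1), beta_adhd = jit(1, 0.3),
      beta_cov = if (!is.null(covs)) jit(ncol(covs), 0.1) else NULL,
      sigma_int2 = 1,
      lambda_adhd = c(1, rep(1, 8) + jit(8, 0.2)),
      alpha_adhd = colMeans(items_adhd),
      theta_adhd = apply(items_adhd, 2, var) / 2,
      lambda_int = c(1, rep(1, 13) + jit(13, 0.2)),
      alpha_int = colMeans(items_int),
      theta_int = apply(items_int, 2, var) / 2,
      lambda_cross = jit(1, 0.2),
      adhd = zrow(items_adhd), eta = zrow(items_int))
  }
  center <- if (model != "none") colMeans(cbind(mu, theta[, c(1, 4, 2, 3),
                                                          drop = FALSE]))
            else rep(0, 6)
  if (!is.null(init_values)) {
    for (nm in intersect(names(init_values), c("mu", "theta", "sigma_w"))) {
      assign(nm, init_values[[nm]])
    }
    for (nm in names(init_values$params)) {
      params[[nm]] <- init_values$params[[nm]]
    }
  }
  list(Y = Y, mu = mu, theta = theta, sigma_w = sigma_w, params = params,
       center = center)
}

draw_names <- function(model, covs, dat, save_person_effects) {
  rn <- re_names()
  if (model == "none") {
    nm <- c(paste0("sigma_w_", c("11", "12", "22")),
            as.vector(outer(rn, seq_len(dat$n),
                            function(a, b) paste0("re_", a, "_", b))))
    return(nm)
  }
  nm <- c(paste0("nu_", rn), paste0("gamma_", rn), paste0("tau2_", rn),
          paste0("sigma_w_", c("11", "12", "22")), "psi_adhd",
          paste0("beta_", rn), "beta_adhd", "sigma_int2",
          paste0("lambda_adhd_", 1:9), paste0("lambda_int_", 1:14),
          "lambda_cross",
          paste0("wstd_", th_names()[c(1, 4, 2, 3)]))
  if (!is.null(covs)) {
    nm <- c(nm,
            as.vector(outer(rn, colnames(covs),
                            function(a, b) paste0("gamma_", b, "_", a))),
            paste0("beta_", colnames(covs)))
  }
  if (save_person_effects) {
    nm <- c(nm, as.vector(outer(rn, seq_len(dat$n),
                                function(a, b) paste0("re_", a, "_", b))))
  }
  nm
}

monitored_params <- function(names_all, model) {
  if (model == "none") return(names_all)
  keep <- grepl("^(nu_|gamma_|beta|sigma_|psi_|tau2_|wstd_|lambda_cross)",
                names_all)
  names_all[keep]
}

# Advance one chain by n_iter iterations, storing every thinning-th draw.
advance_chain <- function(state, dat, items_adhd, items_int, covs, model,
                          cfg, re_prior, sigma_w_mode, fix_sigma_w, priors,
                          n_iter, save_person_effects, nm) {
  n <- dat$n
  rn <- re_names()
  n_store <- n_iter %/% cfg$thinning
  stored <- matrix(NA_real_, n_store, length(nm),
                   dimnames = list(NULL, nm))
  srow <- 0
  degen <- which(dat$last - dat$first < 2)

  for (it in seq_len(n_iter)) {
    store_this <- it %% cfg$thinning == 0
    p <- state$params

    if (model == "none") {
      pr_mean <- matrix(re_prior$mean[rn], n, 6, byrow = TRUE,
                        dimnames = list(NULL, rn))
      pr_var <- matrix(re_prior$var[rn], n, 6, byrow = TRUE,
                       dimnames = list(NULL, rn))
      beta_mu <- c(0, 0); beta_th <- rep(0, 4)
      eta_off <- rep(0, n); sigma_int2 <- 1; use_eta <- FALSE
    } else {
      pr_mean <- matrix(p$nu, n, 6, byrow = TRUE) +
        outer(p$adhd, p$gamma_adhd)
      if (!is.null(covs)) pr_mean <- pr_mean + covs %*% t(p$gamma_cov)
      colnames(pr_mean) <- rn
      pr_var <- matrix(p$tau2, n, 6, byrow = TRUE, dimnames = list(NULL, rn))
      beta_mu <- p$beta_int[1:2]
      beta_th <- p$beta_int[th_in_re()]
      eta_off <- p$eta - p$beta0 + sum(p$beta_int * state$center) -
        p$beta_adhd * p$adhd -
        if (!is.null(covs)) as.numeric(covs %*% p$beta_cov) else 0
      sigma_int2 <- p$sigma_int2
      use_eta <- TRUE
    }

    sw <- within_sweep(
      state$Y, dat$obs1, dat$obs2, dat$first, dat$last,
      state$mu, state$theta, state$sigma_w,
      prior_mu_mean = pr_mean[, 1:2, drop = FALSE],
      prior_mu_prec = 1 / pr_var[, 1:2, drop = FALSE],
      prior_th_mean = pr_mean[, th_in_re(), drop = FALSE],
      prior_th_prec = 1 / pr_var[, th_in_re(), drop = FALSE],
      beta_mu = beta_mu, beta_th = beta_th, eta_off = eta_off,
      sigma_eta2 = sigma_int2, use_eta = use_eta,
      update_states = TRUE, update_mu = TRUE, update_theta = TRUE,
      compute_derived = store_this && model != "none")
    state$mu <- sw$mu
    state$theta <- sw$theta

    # persons with too few transitions: prior draw (logged via status)
    if (length(degen) > 0) {
      for (i in degen) {
        state$mu[i, ] <- rnorm(2, pr_mean[i, 1:2], sqrt(pr_var[i, 1:2]))
        state$theta[i, ] <- rnorm(4, pr_mean[i, th_in_re()],
                                  sqrt(pr_var[i, th_in_re()]))
      }
    }

    if (sigma_w_mode == "estimate") {
      state$sigma_w <- riwish(priors$iw_df + sw$n_trans,
                              priors$iw_scale + sw$sse)
    } else if (sigma_w_mode == "diagonal") {
      state$sigma_w <- diag(c(
        rinvgamma1(priors$ig_a + sw$n_trans / 2, priors$ig_b + sw$sse[1, 1] / 2),
        rinvgamma1(priors$ig_a + sw$n_trans / 2, priors$ig_b + sw$sse[2, 2] / 2)))
    } else {
      state$sigma_w <- fix_sigma_w
    }

    re <- cbind(state$mu, state$theta[, c(1, 4, 2, 3), drop = FALSE])
    colnames(re) <- rn

    if (model != "none") {
      state$params <- sample_between(re, items_adhd, items_int, covs,
                                     state$params,
                                     cross_idx = attr(items_adhd, "cross_idx"),
                                     center = state$center, priors = priors)
      # non-centered scale moves for the random-effect residual SDs,
      # using the conditional prior means implied by the updated
      # between-level parameters
      p2 <- state$params
      pm2 <- matrix(p2$nu, n, 6, byrow = TRUE) + outer(p2$adhd, p2$gamma_adhd)
      if (!is.null(covs)) pm2 <- pm2 + covs %*% t(p2$gamma_cov)
      mv <- re_scale_moves(state$mu, state$theta, p2$tau2, sw$pstats, pm2,
                           p2, covs, state$sigma_w, priors,
                           center = state$center)
      state$mu <- mv$mu
      state$theta <- mv$theta
      state$params$tau2 <- mv$tau2
    }

    if (store_this) {
      srow <- srow + 1
      p <- state$params
      swv <- c(state$sigma_w[1, 1], state$sigma_w[1, 2], state$sigma_w[2, 2])
      if (model == "none") {
        stored[srow, ] <- c(swv, as.vector(t(re)))
      } else {
        v <- c(p$nu, p$gamma_adhd, p$tau2, swv, p$psi_adhd,
               p$beta_int, p$beta_adhd, p$sigma_int2,
               p$lambda_adhd, p$lambda_int, p$lambda_cross, sw$wstd)
        if (!is.null(covs)) v <- c(v, as.vector(p$gamma_cov), p$beta_cov)
        if (save_person_effects) v <- c(v, as.vector(t(re)))
        stored[srow, ] <- v
      }
    }
  }
  list(state = state, stored = stored)
}

#' Fit the dynamic structural equation model by MCMC
#'
#' Runs independent Gibbs chains for the two-level model: latent within-person
#' lag-1 dynamics of stress and negative affect with person-specific means,
#' autoregressive and cross-lagged coefficients; those six random effects
#' regressed on a latent ADHD factor (and optionally sex, caregiver origin and
#' SES); and a latent internalising factor regressed on the random effects
#' and ADHD. Missing grid cells are imputed from their conditional posterior.
#' Convergence is monitored by the potential scale reduction of all
#' population-level parameters; once every PSR first falls below the
#' threshold, the completed iteration count is doubled before stopping
#' (configurable).
#'
#' @param aligned an `aligned_ema` tibble from [align_ema()].
#' @param persons person-level tibble with the trait items and covariates
#'   (not needed for `model = "none"`).
#' @param model `"baseline"` (random effects predicted by latent ADHD only),
#'   `"covariates"` (additionally sex, caregiver country of origin and
#'   z-scored childhood SES on every random effect and on internalising), or
#'   `"none"` (no between-person structure; random effects draw their prior
#'   from `re_prior` — used for oracle checks).
#' @param config an [mcmc_config()].
#' @param sigma_w_mode innovation covariance: `"estimate"` (inverse-Wishart
#'   update with free off-diagonal), `"diagonal"`, or `"fixed"`.
#' @param fix_sigma_w the fixed innovation covariance when
#'   `sigma_w_mode = "fixed"`.
#' @param re_prior for `model = "none"`: list with named 6-vectors `mean` and
#'   `var`.
#' @param cross_item trait item carrying the cross-loading on internalising.
#' @param save_person_effects also store each person's random-effect draws
#'   (memory-heavy; intended for small runs).
#' @param init_values optional list overriding starting values: `mu`,
#'   `theta`, `sigma_w` and/or a `params` sub-list of between-level starting
#'   values; applied to every chain after the data-derived defaults.
#' @param priors hyperparameters: `loc_prec` (precision of the normal prior
#'   on intercepts, default 1e-6), `slope_prec` (precision of the normal
#'   prior on loadings and regression slopes; the default 0.04, i.e.
#'   Normal(0, 25), is weakly informative and keeps the latent factor scale
#'   proper), `ig_a`, `ig_b` (inverse-gamma shape/rate on variances; the
#'   default a = -1/2, b = 0 is the uniform-on-SD prior, which avoids the
#'   near-1/x spike of IG(eps, eps) that biases weakly identified variance
#'   components toward zero),
#'   `iw_df`, `iw_scale` (inverse-Wishart prior on the innovation
#'   covariance, default df 3 and identity scale).
#' @return A `dsem_fit` object: per-chain stored draws, retained post-burn-in
#'   draws, the PSR table, convergence status and run metadata.
#' @export
run_mcmc <- function(aligned, persons = NULL,
                     model = c("baseline", "covariates", "none"),
                     config = mcmc_config(),
                     sigma_w_mode = c("estimate", "diagonal", "fixed"),
                     fix_sigma_w = NULL, re_prior = NULL,
                     cross_item = "adhd5", save_person_effects = FALSE,
                     init_values = NULL,
                     priors = list(loc_prec = 1e-6, slope_prec = 0.04,
                                   ig_a = -0.5, ig_b = 0, iw_df = 3,
                                   iw_scale = diag(2))) {
  model <- match.arg(model)
  sigma_w_mode <- match.arg(sigma_w_mode)
  if (sigma_w_mode == "fixed") stopifnot(!is.null(fix_sigma_w))
  if (model == "none") stopifnot(!is.null(re_prior))
  cfg <- config
  t0 <- Sys.time()

  dat <- prepare_series(aligned)
  items_adhd <- items_int <- covs <- NULL
  if (model != "none") {
    stopifnot(!is.null(persons))
    items_adhd <- as.matrix(persons[, paste0("adhd", 1:9)])
    items_int <- as.matrix(persons[, paste0("int", 1:14)])
    attr(items_adhd, "cross_idx") <- match(cross_item, paste0("adhd", 1:9))
    if (model == "covariates") {
      covs <- cbind(sex = persons$sex, origin = persons$origin,
                    ses_z = as.numeric(scale(persons$ses)))
    }
  }

  set.seed(cfg$seed)
  chain_seeds <- sample.int(2^30, cfg$n_chains)   # headroom for +iteration offsets
  states <- lapply(chain_seeds, function(s) {
    init_chain(dat, items_adhd, items_int, covs, model, cfg, re_prior, s,
               init_values = init_values)
  })
  nm <- draw_names(model, covs, dat, save_person_effects)
  mon <- monitored_params(nm, model)
  stored <- replicate(cfg$n_chains,
                      matrix(NA_real_, 0, length(nm),
                             dimnames = list(NULL, nm)),
                      simplify = FALSE)

  iter_done <- 0
  first_conv <- NA_integer_
  target <- cfg$max_iterations
  repeat {
    block <- min(cfg$check_every, target - iter_done)
    if (block <= 0) break
    for (c in seq_len(cfg$n_chains)) {
      set.seed(chain_seeds[c] + 1L + iter_done)   # per-block reseed per chain
      adv <- advance_chain(states[[c]], dat, items_adhd, items_int, covs,
                           model, cfg, re_prior, sigma_w_mode, fix_sigma_w,
                           priors, block, save_person_effects, nm)
      states[[c]] <- adv$state
      stored[[c]] <- rbind(stored[[c]], adv$stored)
    }
    iter_done <- iter_done + block

    if (cfg$n_chains >= 2 && is.na(first_conv) &&
        iter_done >= cfg$min_iterations) {
      n_st <- nrow(stored[[1]])
      if (n_st >= 20) {
        half <- lapply(stored, function(m) {
          m[(floor(n_st / 2) + 1):n_st, mon, drop = FALSE]
        })
        r <- suppressWarnings(psr(half))
        if (all(is.finite(r)) && all(r < cfg$psr_threshold)) {
          first_conv <- iter_done
          target <- if (cfg$double_on_first_convergence) {
            min(2 * iter_done, cfg$max_iterations)
          } else iter_done
        }
      }
    }
    if (iter_done >= target) break
  }

  burn <- floor(nrow(stored[[1]]) * cfg$burn_in_fraction)
  retained <- lapply(stored, function(m) m[(burn + 1):nrow(m), , drop = FALSE])
  psr_final <- if (cfg$n_chains >= 2 && nrow(retained[[1]]) >= 10) {
    suppressWarnings(psr(lapply(retained, function(m) m[, mon, drop = FALSE])))
  } else NULL
  converged <- !is.null(psr_final) && all(is.finite(psr_final)) &&
    all(psr_final < cfg$psr_threshold)
  if (!converged) {
    warning("Chains did not reach the PSR threshold; treat estimates with caution.",
            call. = FALSE)
  }

  structure(list(
    draws = stored, retained = retained, psr = psr_final,
    monitored = mon, model = model, config = cfg,
    status = list(converged = converged, iterations = iter_done,
                  first_convergence = first_conv,
                  n_retained = nrow(retained[[1]]),
                  n_degenerate_persons = sum(dat$last - dat$first < 2)),
    data_info = list(
      n_persons = dat$n, t_max = dat$t_max,
      cov_names = if (!is.null(covs)) colnames(covs) else NULL,
      cov_cov = if (!is.null(covs)) cov(covs) else NULL),
    seeds = chain_seeds, sigma_w_mode = sigma_w_mode,
    runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "dsem_fit")
}

#' @export
print.dsem_fit <- function(x, ...) {
  cat("<dsem_fit>", x$model, "model,", length(x$draws), "chains,",
      x$status$iterations, "iterations,",
      x$status$n_retained, "retained draws/chain\n")
  cat("  converged:", x$status$converged,
      if (!is.null(x$psr)) sprintf("(max PSR %.3f)", max(x$psr)), "\n")
  invisible(x)
}

# Pool retained draws across chains into one matrix.
pooled_draws <- function(fit) do.call(rbind, fit$retained)
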