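# Shared fixtures: small designs and generating models used across tests.
# Everything is built in code at test time; no stored data.

small_config <- function(n_persons = 8, n_days = 3, seed = 42, ...) {
  design_config(n_persons = n_persons, n_days = n_days, seed = seed, ...)
}

# A generating model with mild dynamics, cheap to fit.
small_truth <- function(...) true_model(...)

# Aligned series for one person directly on the grid (no gaps).
grid_series <- function(stress, affect, person_id = 1L, delta = 240,
                        origin = 600) {
  n <- length(stress)
  out <- tibble::tibble(person_id = person_id, slot = 0:(n - 1L),
                        time = origin + delta * 0:(n - 1L),
                        stress = stress, affect = affect)
  class(out) <- c("aligned_ema", class(out))
  out
}

# Independent bivariate-normal log-density for oracle checks.
ref_ldmvnorm <- function(x, mean, sigma) {
  k <- length(x)
  -0.5 * (k * log(2 * pi) + determinant(sigma)$modulus +
            t(x - mean) %*% solve(sigma) %*% (x - mean))[1]
}

re_vec <- function(mu_s = 0, mu_a = 0, phi_ss = 0, phi_aa = 0,
                   phi_as = 0, phi_sa = 0) {
  c(mu_s = mu_s, mu_a = mu_a, phi_ss = phi_ss, phi_aa = phi_aa,
    phi_as = phi_as, phi_sa = phi_sa)
}

# Continuous two-factor item data for CFA tests.
sim_cfa_data <- function(n, lambda1, lambda2, phi12 = 0.4, resid_sd = NULL,
                         seed = 1) {
  set.seed(seed)
  p1 <- length(lambda1); p2 <- length(lambda2)
  f <- rmvnorm_chol(n, c(0, 0), matrix(c(1, phi12, phi12, 1), 2))
  resid_sd <- resid_sd %||% rep(0.7, p1 + p2)
  y <- cbind(f[, 1] %o% lambda1, f[, 2] %o% lambda2) +
    matrix(rnorm(n * (p1 + p2)), n) * rep(resid_sd, each = n)
  colnames(y) <- c(paste0("x", seq_len(p1)), paste0("z", seq_len(p2)))
  tibble::as_tibble(y)
}

`%||%` <- rlang::`%||%`

# Minimal hand-built fit object with the draw columns the reporting layer
# needs; lets tests pin exact expected values.
fake_fit <- function(draws, cov_names = NULL, cov_cov = NULL,
                     converged = TRUE, model = "baseline") {
  stopifnot(is.matrix(draws))
  structure(list(
    draws = list(draws), retained = list(draws), psr = NULL,
    monitored = colnames(draws), model = model,
    config = mcmc_config(),
    status = list(converged = converged, iterations = nrow(draws),
                  first_convergence = NA, n_retained = nrow(draws),
                  n_degenerate_persons = 0),
    data_info = list(n_persons = 100, t_max = 10, cov_names = cov_names,
                     cov_cov = cov_cov),
    seeds = 1, sigma_w_mode = "estimate", runtime = 0), class = "dsem_fit")
}

draw_cols <- function(n, overrides = list()) {
  rn <- c("mu_s", "mu_a", "phi_ss", "phi_aa", "phi_as", "phi_sa")
  cols <- c(paste0("nu_", rn), paste0("gamma_", rn), paste0("tau2_", rn),
            paste0("sigma_w_", c("11", "12", "22")), "psi_adhd",
            paste0("beta_", rn), "beta_adhd", "sigma_int2",
            paste0("lambda_adhd_", 1:9), paste0("lambda_int_", 1:14),
            "lambda_cross", paste0("wstd_", c("phi_ss", "phi_aa", "phi_as",
                                              "phi_sa")))
  m <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  m[, paste0("tau2_", rn)] <- 1
  m[, "psi_adhd"] <- 1
  m[, "sigma_int2"] <- 1
  for (nm in names(overrides)) m[, nm] <- overrides[[nm]]
  m
}

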