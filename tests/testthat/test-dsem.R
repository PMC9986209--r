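# Gibbs building blocks: within-person likelihood, state imputation,
# random-effect conditionals, PSR diagnostic.

test_that("within_loglik matches standard-normal and hand-computed densities", {
  # zero deviations, identity innovations: each transition contributes
  # -log(2*pi); 11 observations = 10 transitions
  y <- matrix(0, 11, 2)
  expect_equal(within_loglik(y, re_vec(), diag(2)), -10 * log(2 * pi))

  # single transition against an independent bivariate normal evaluation
  re <- re_vec(mu_s = 1, mu_a = -2, phi_ss = 0.4, phi_aa = 0.2,
               phi_as = 0.1, phi_sa = -0.3)
  sw <- matrix(c(1.5, 0.4, 0.4, 0.9), 2)
  y <- rbind(c(2.0, -1.0), c(0.5, -2.5))
  x_prev <- y[1, ] - c(1, -2)
  x_curr <- y[2, ] - c(1, -2)
  mean_or <- c(0.4 * x_prev[1] + 0.1 * x_prev[2],
               -0.3 * x_prev[1] + 0.2 * x_prev[2])
  expect_equal(within_loglik(y, re, sw), ref_ldmvnorm(x_curr, mean_or, sw))
})

test_that("within_loglik is invariant to joint location shifts", {
  set.seed(31)
  re <- re_vec(mu_s = 9, mu_a = 12, phi_ss = 0.3, phi_aa = 0.2)
  sw <- diag(c(2, 3))
  y <- cbind(rnorm(30, 9, 2), rnorm(30, 12, 2))
  re2 <- re; re2[["mu_s"]] <- re[["mu_s"]] + 5; re2[["mu_a"]] <- re[["mu_a"]] - 3
  y2 <- sweep(y, 2, c(5, -3), `+`)
  expect_equal(within_loglik(y, re, sw), within_loglik(y2, re2, sw))
})

test_that("sample_latent_states returns observed data unchanged", {
  set.seed(32)
  y <- cbind(rnorm(10), rnorm(10))
  expect_identical(sample_latent_states(y, re_vec(phi_ss = 0.3), diag(2)), y)
})

test_that("a single imputed slot matches joint-Gaussian conditioning", {
  re <- re_vec(phi_ss = 0.5, phi_aa = 0.3, phi_as = 0.2, phi_sa = 0.1)
  phi <- matrix(c(0.5, 0.2, 0.1, 0.3), 2, 2, byrow = TRUE)
  sw <- matrix(c(1, 0.3, 0.3, 1.4), 2)
  y_obs <- rbind(c(1.2, -0.4), c(NA, NA), c(-0.8, 0.6))
  # oracle: stationary joint of (x1, x2, x3), condition the middle block
  s0 <- stationary_cov(phi, sw)
  g1 <- phi %*% s0                       # Cov(x_{t+1}, x_t)
  g2 <- phi %*% g1
  J <- rbind(cbind(s0, t(g1), t(g2)),
             cbind(g1, s0, t(g1)),
             cbind(g2, g1, s0))
  io <- c(1, 2, 5, 6); im <- c(3, 4)
  cond_mean <- J[im, io] %*% solve(J[io, io], c(y_obs[1, ], y_obs[3, ]))
  cond_var <- J[im, im] - J[im, io] %*% solve(J[io, io], J[io, im])
  set.seed(33)
  draws <- t(replicate(20000, sample_latent_states(y_obs, re, sw)[2, ]))
  se_mean <- sqrt(diag(cond_var) / nrow(draws))
  expect_true(all(abs(colMeans(draws) - cond_mean) < 4 * se_mean))
  expect_equal(cov(draws), cond_var, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("imputed states far inside a long gap reach the stationary law", {
  re <- re_vec(phi_ss = 0.5, phi_aa = 0.2)
  phi <- matrix(c(0.5, 0, 0, 0.2), 2, 2)
  sw <- diag(2)
  y <- rbind(c(0.3, -0.2), matrix(NA, 11, 2), c(-0.5, 0.1))
  # the middle of the gap is 6 transitions from either endpoint; with
  # phi = 0.5 the conditional there is the stationary law to within 2%
  set.seed(34)
  mids <- replicate(250, sample_latent_states(y, re, sw, sweeps = 250)[7, 1])
  s_stat <- stationary_cov(phi, sw)
  expect_lt(abs(mean(mids)), 3 * sqrt(s_stat[1, 1] / 250))
  expect_equal(var(mids), s_stat[1, 1], tolerance = 0.25)
})

test_that("random-effect draws match the scalar conjugate posterior", {
  set.seed(35)
  T_n <- 60
  s <- as.numeric(arima.sim(list(ar = 0.45), T_n))
  y <- cbind(s, 0)
  pm <- re_vec(); pv <- re_vec(mu_s = 1e-10, mu_a = 1e-10, phi_ss = 1,
                               phi_aa = 1e-10, phi_as = 1e-10, phi_sa = 1)
  draws <- replicate(4000, sample_random_effects(
    y, pm, pv, diag(2), current = pm, blocks = "phi")[["phi_ss"]])
  # closed form: phi | data ~ N(sxy / (sxx + 1), 1 / (sxx + 1))
  sxx <- sum(s[-T_n]^2); sxy <- sum(s[-T_n] * s[-1])
  m_star <- sxy / (sxx + 1); v_star <- 1 / (sxx + 1)
  expect_lt(abs(mean(draws) - m_star), 3 * sqrt(v_star / 4000))
  expect_equal(var(draws), v_star, tolerance = 0.1)
})

test_that("random effects fall back to the prior with too few transitions", {
  pm <- re_vec(mu_s = 2, phi_ss = 0.3)
  pv <- re_vec(mu_s = 0.5, mu_a = 0.5, phi_ss = 0.04, phi_aa = 0.04,
               phi_as = 0.04, phi_sa = 0.04)
  set.seed(36)
  expect_message(sample_random_effects(matrix(0, 2, 2), pm, pv, diag(2)),
                 "prior")
  draws <- suppressMessages(
    replicate(3000, sample_random_effects(matrix(0, 2, 2), pm, pv,
                                          diag(2))[["mu_s"]]))
  expect_lt(abs(mean(draws) - 2), 3 * sqrt(0.5 / 3000))
  expect_equal(var(draws), 0.5, tolerance = 0.1)
})

test_that("with long series the posterior concentrates on least squares", {
  set.seed(37)
  re_true <- re_vec(mu_s = 3, mu_a = 5, phi_ss = 0.4, phi_aa = 0.25,
                    phi_as = 0.15, phi_sa = 0.1)
  sw <- diag(c(1, 1.3))
  x <- simulate_person_series(re_true, sw, 4000)
  y <- sweep(x, 2, c(3, 5), `+`)
  pm <- re_vec(); pv <- re_vec(1e6, 1e6, 1e6, 1e6, 1e6, 1e6)
  d <- rowMeans(replicate(60, sample_random_effects(y, pm, pv, sw,
                                                    current = re_true)))
  # least-squares oracle via lm()
  xs <- x[-nrow(x), 1]; xa <- x[-nrow(x), 2]
  ols_s <- coef(lm(x[-1, 1] ~ 0 + xs + xa))
  ols_a <- coef(lm(x[-1, 2] ~ 0 + xs + xa))
  expect_lt(abs(d[["phi_ss"]] - ols_s[[1]]), 0.02)
  expect_lt(abs(d[["phi_as"]] - ols_s[[2]]), 0.02)
  expect_lt(abs(d[["phi_sa"]] - ols_a[[1]]), 0.02)
  expect_lt(abs(d[["mu_s"]] - 3), 0.2)
})

test_that("psr detects identical, offset and well-mixed chains", {
  set.seed(38)
  base <- matrix(rnorm(5000), 1000, 5,
                 dimnames = list(NULL, paste0("p", 1:5)))
  expect_true(all(as.numeric(psr(list(base, base))) == 1))
  off <- base; off[, 1] <- off[, 1] + 50
  expect_gt(psr(list(base, off))[["p1"]], 10)
  iid <- replicate(2, matrix(rnorm(1e4), ncol = 1), simplify = FALSE)
  expect_lt(psr(iid)[[1]], 1.01)
  # zero within-chain variance flagged
  con <- matrix(1, 100, 1)
  r <- psr(list(con, con))
  expect_equal(unname(r[1]), 1)
  expect_length(attr(r, "degenerate"), 1)
  r2 <- psr(list(con, con + 1))
  expect_true(is.infinite(r2[1]))
})
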