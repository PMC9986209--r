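# Standardisation, indirect effects, results table.

test_that("standardisation is the identity on the unit scale", {
  # gamma = 0.3 with tau2 = 1 - 0.3^2 makes sd(r) = 1; beta_adhd = 0.6 with
  # sigma_int2 chosen so sd(eta) = 1
  m <- draw_cols(50, list(gamma_mu_s = 0.3, tau2_mu_s = 1 - 0.09,
                          beta_adhd = 0.6, sigma_int2 = 1 - 0.36))
  std <- standardize_draws(fake_fit(m))
  expect_equal(std$std_gamma_mu_s, rep(0.3, 50))
  expect_equal(std$std_beta_adhd, rep(0.6, 50))
})

test_that("standardised between effects follow b * sd(x) / sd(y)", {
  set.seed(41)
  n <- 200
  g <- rnorm(n, 0.5, 0.05); t2 <- runif(n, 0.5, 1.5); psi <- runif(n, 0.5, 2)
  m <- draw_cols(n, list(gamma_mu_a = g, tau2_mu_a = t2, psi_adhd = psi))
  std <- standardize_draws(fake_fit(m))
  expect_equal(std$std_gamma_mu_a, g * sqrt(psi) / sqrt(g^2 * psi + t2))
  # outcome standardisation for the internalising regression
  b <- rnorm(n, 0.4, 0.05); s2 <- runif(n, 0.3, 0.8)
  m2 <- draw_cols(n, list(beta_mu_a = b, sigma_int2 = s2))
  std2 <- standardize_draws(fake_fit(m2))
  sd_eta <- sqrt(b^2 * 1 + s2)            # var(r) = 1, no other paths
  expect_equal(std2$std_beta_mu_a, b * 1 / sd_eta)
})

test_that("standardised estimates are invariant to unit relabelling", {
  set.seed(42)
  n <- 100
  g <- rnorm(n, 0.4, 0.04); t2 <- runif(n, 0.8, 1.2); b <- rnorm(n, 0.3, 0.03)
  m1 <- draw_cols(n, list(gamma_mu_s = g, tau2_mu_s = t2, beta_mu_s = b))
  # stress scale x10: gamma x10, tau2 x100, beta / 10
  m2 <- draw_cols(n, list(gamma_mu_s = 10 * g, tau2_mu_s = 100 * t2,
                          beta_mu_s = b / 10))
  s1 <- standardize_draws(fake_fit(m1))
  s2 <- standardize_draws(fake_fit(m2))
  expect_equal(s1$std_gamma_mu_s, s2$std_gamma_mu_s)
  expect_equal(s1$std_beta_mu_s, s2$std_beta_mu_s)
})

test_that("indirect effects are within-draw products", {
  # degenerate posterior: a = 0.2, b = 0.3 -> product exactly 0.06
  m <- draw_cols(40, list(gamma_phi_ss = 0.2, beta_phi_ss = 0.3))
  ie <- indirect_effects(fake_fit(m))
  row <- ie[ie$label == "via AR: Stress -> Stress", ]
  expect_equal(row$estimate, 0.06)
  expect_equal(row$ci_lower, 0.06)
  # a = 0 everywhere -> indirect 0, CI contains 0
  m0 <- draw_cols(40, list(beta_phi_ss = rnorm(40, 0.3, 0.05)))
  r0 <- indirect_effects(fake_fit(m0))[1:6, ]
  expect_true(all(r0$estimate == 0))
  expect_false(any(r0$significant))
})

test_that("independent draws give product moments E(ab) = E(a)E(b)", {
  set.seed(43)
  n <- 20000
  a <- rnorm(n, 0.25, 0.1); b <- rnorm(n, 0.4, 0.2)
  m <- draw_cols(n, list(gamma_mu_a = a, beta_mu_a = b))
  ie <- indirect_effects(fake_fit(m))
  row <- ie[ie$label == "via M: Affect", ]
  prod_sd <- sqrt(0.25^2 * 0.2^2 + 0.4^2 * 0.1^2 + 0.1^2 * 0.2^2)
  expect_lt(abs(mean(row$draws[[1]]) - 0.25 * 0.4), 4 * prod_sd / sqrt(n))
  expect_equal(sd(row$draws[[1]]), prod_sd, tolerance = 0.03)
})

test_that("the product CI comes from per-draw products, not endpoint products", {
  set.seed(44)
  n <- 5000
  a <- rnorm(n, 1, 0.3)
  b <- 2 - a + rnorm(n, 0, 0.01)          # strongly negatively coupled
  m <- draw_cols(n, list(gamma_mu_s = a, beta_mu_s = b))
  ie <- indirect_effects(fake_fit(m))
  row <- ie[ie$label == "via M: Stress", ]
  oracle <- unname(quantile(a * b, c(0.025, 0.975)))
  expect_equal(c(row$ci_lower, row$ci_upper), oracle)
  naive <- quantile(a, 0.025) * quantile(b, 0.025)
  expect_gt(abs(naive - oracle[1]), 0.1)  # endpoints product would mislead
})

test_that("significance flags flip exactly when the CI crosses zero", {
  set.seed(45)
  z <- rnorm(400)
  for (shift in c(-1, 0, 3)) {
    m <- draw_cols(400, list(gamma_mu_s = z + shift))
    tab <- make_table(fake_fit(m))
    row <- tab[tab$block == "Effect of ADHD on" & tab$label == "M: Stress", ]
    q <- quantile(z + shift, c(0.025, 0.975))
    expect_equal(unname(row$significant), unname(q[1] > 0 | q[2] < 0))
  }
})

test_that("wider credible levels give wider intervals", {
  set.seed(46)
  m <- draw_cols(2000, list(gamma_mu_s = rnorm(2000, 0.3, 0.1)))
  f <- fake_fit(m)
  t95 <- make_table(f, level = 0.95)
  t99 <- make_table(f, level = 0.99)
  w95 <- t95$ci_upper - t95$ci_lower
  w99 <- t99$ci_upper - t99$ci_lower
  expect_true(all(w99 >= w95))
})

test_that("the results table round-trips through CSV", {
  m <- draw_cols(100, list(gamma_mu_s = rnorm(100, 0.3, 0.1),
                           beta_adhd = rnorm(100, 0.4, 0.1)))
  tab <- make_table(fake_fit(m))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back[, c("block", "label", "estimate",
                                      "ci_lower", "ci_upper")]),
               as.data.frame(tab[, c("block", "label", "estimate",
                                     "ci_lower", "ci_upper")]),
               tolerance = 1e-12)
  expect_equal(back$significant, tab$significant)
})

test_that("empty draw sets are rejected", {
  m <- draw_cols(0)
  expect_error(make_table(fake_fit(m)), "draws|rows|empty")
})
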