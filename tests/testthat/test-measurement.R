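# Scale scoring, confirmatory factor model, fit indices, omega.

test_that("score_scales sums rows and propagates missing items", {
  items <- tibble::tibble(a = c(1, 5, 2, NA), b = c(1, 5, 3, 2),
                          c = c(1, 5, 4, 1), d = c(1, 5, 1, 5))
  s <- score_scales(items, list(total = c("a", "b", "c", "d")))
  expect_equal(s$total, c(4, 20, 10, NA))
  items7 <- tibble::as_tibble(as.data.frame(matrix(5, 2, 7)))
  expect_equal(score_scales(items7, list(aff = names(items7)))$aff, c(35, 35))
  expect_error(score_scales(tibble::tibble(a = 6, b = 1),
                            list(s = c("a", "b"))), "range")
})

test_that("omega follows the closed form and handles the one-item edge", {
  mk_fit <- function(lambda, theta, psi = 1) {
    p <- length(lambda)
    structure(list(
      spec = cfa_spec(list(f = paste0("x", 1:p))),
      lambda = matrix(lambda, p, 1, dimnames = list(paste0("x", 1:p), "f")),
      psi = matrix(psi, 1, 1, dimnames = list("f", "f")),
      theta = stats::setNames(theta, paste0("x", 1:p))), class = "cfa_fit")
  }
  # 9 equal loadings 0.7, residuals 0.51: (9*0.7)^2 / ((9*0.7)^2 + 9*0.51)
  expect_equal(omega(mk_fit(rep(0.7, 9), rep(0.51, 9)), "f"),
               6.3^2 / (6.3^2 + 9 * 0.51))
  expect_equal(omega(mk_fit(1, 1), "f"), 0.5)
  # residual variances -> 0 drives omega -> 1
  expect_gt(omega(mk_fit(rep(0.7, 5), rep(1e-8, 5)), "f"), 0.9999)
})

test_that("CFA recovers generating loadings and fits a correct model", {
  lam1 <- c(1, 0.8, 1.2, 0.9, 0.7)
  lam2 <- c(1, 1.1, 0.85, 0.95)
  d <- sim_cfa_data(2000, lam1, lam2, phi12 = 0.4, seed = 21)
  spec <- cfa_spec(list(f1 = paste0("x", 1:5), f2 = paste0("z", 1:4)))
  fit <- fit_cfa(d, spec)
  expect_true(fit$converged)
  expect_false(fit$heywood)
  expect_gt(fit$fit$cfi, 0.99)
  est <- fit$lambda[, "f1"][paste0("x", 2:5)]
  se <- fit$lambda_se[, "f1"][paste0("x", 2:5)]
  expect_true(all(abs(est - lam1[2:5]) < 3 * se))
  expect_equal(fit$psi["f1", "f2"], 0.4, tolerance = 0.1)
  # reference loadings exactly 1
  expect_equal(unname(fit$lambda["x1", "f1"]), 1)
  expect_equal(unname(fit$lambda["z1", "f2"]), 1)
})

test_that("omega is invariant to the choice of reference indicator", {
  d <- sim_cfa_data(1500, c(1, 0.8, 1.2, 0.9), c(1, 1.1, 0.9), seed = 22)
  f_a <- fit_cfa(d, cfa_spec(list(f1 = c("x1", "x2", "x3", "x4"),
                                  f2 = c("z1", "z2", "z3"))), se = FALSE)
  f_b <- fit_cfa(d, cfa_spec(list(f1 = c("x3", "x2", "x1", "x4"),
                                  f2 = c("z1", "z2", "z3"))), se = FALSE)
  expect_equal(omega(f_a, "f1"), omega(f_b, "f1"), tolerance = 1e-3)
})

test_that("fit indices: saturated model gives chi2 = 0 and CFI = 1", {
  fi <- fit_indices(chi2_m = 0, df_m = 0, chi2_b = 900, df_b = 36, n = 500,
                    m2ll = 1000, k = 20)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$tli, 1)
  # CFI formula against a hand computation
  fi2 <- fit_indices(120, 60, 900, 66, 500)
  expect_equal(fi2$cfi, 1 - (120 - 60) / (900 - 66))
  expect_equal(fi2$rmsea, sqrt((120 - 60) / (60 * 500)))
})

test_that("delta_BIC equals the difference computed from log-likelihoods", {
  d <- sim_cfa_data(400, c(1, 0.9, 1.1), c(1, 0.8, 1.2), seed = 23)
  s1 <- cfa_spec(list(f1 = paste0("x", 1:3), f2 = paste0("z", 1:3)))
  s2 <- cfa_spec(list(f1 = paste0("x", 1:3), f2 = paste0("z", 1:3)),
                 cross = list(x2 = "f2"))
  f1 <- fit_cfa(d, s1, se = FALSE)
  f2 <- fit_cfa(d, s2, se = FALSE)
  # independent -2logL recomputation from the fitted moments
  m2ll_of <- function(f, d) {
    y <- as.matrix(d)
    sigma <- f$lambda %*% f$psi %*% t(f$lambda) + diag(f$theta)
    ll <- sum(apply(y, 1, function(r) ref_ldmvnorm(r, f$nu, sigma)))
    -2 * ll
  }
  bic_ind <- function(f, d) m2ll_of(f, d) + f$k * log(nrow(d))
  expect_equal(delta_bic(f1, f2), bic_ind(f1, d) - bic_ind(f2, d),
               tolerance = 1e-6)
})

test_that("FIML CFA handles missing items without dropping cases", {
  d <- sim_cfa_data(600, c(1, 0.9, 1.1, 0.8), c(1, 1.2, 0.9), seed = 24)
  d_miss <- d
  set.seed(25)
  for (j in seq_along(d_miss)) {
    d_miss[[j]][sample(600, 40)] <- NA
  }
  spec <- cfa_spec(list(f1 = paste0("x", 1:4), f2 = paste0("z", 1:3)))
  fit <- fit_cfa(d_miss, spec, se = FALSE)
  expect_true(fit$converged)
  full <- fit_cfa(d, spec, se = FALSE)
  expect_equal(fit$lambda[fit$lambda != 0], full$lambda[full$lambda != 0],
               tolerance = 0.12)
})

test_that("tidy and glance expose loadings and fit", {
  d <- sim_cfa_data(300, c(1, 0.9, 1.1), c(1, 0.8, 1.2), seed = 26)
  fit <- fit_cfa(d, cfa_spec(list(f1 = paste0("x", 1:3),
                                  f2 = paste0("z", 1:3))), se = FALSE)
  td <- tidy(fit)
  expect_true(all(c("factor", "item", "loading", "reference") %in% names(td)))
  expect_equal(sum(td$reference), 2)
  gl <- glance(fit)
  expect_true(all(c("cfi", "tli", "rmsea", "bic", "converged") %in% names(gl)))
})
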