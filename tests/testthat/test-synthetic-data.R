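# Synthetic EMA generator: schedules, latent dynamics, traits, composition.

test_that("design_config validates the prompt window", {
  expect_s3_class(design_config(), "design_config")
  expect_error(design_config(window_start = 22, window_end = 10), "later")
  expect_error(design_config(prompts_per_day = 30, min_gap = 30),
               "too small")
  expect_error(design_config(compliance = 1.3))
})

test_that("sample_schedule issues ordered in-window prompts with the minimum gap", {
  cfg <- design_config(n_persons = 20, n_days = 5, seed = 7)
  sch <- sample_schedule(cfg)
  expect_equal(nrow(sch), 20 * 5 * 4)
  tod <- sch$time %% 1440
  expect_true(all(tod >= 10 * 60 & tod <= 22 * 60))
  gaps <- sch |>
    dplyr::group_by(person_id, day) |>
    dplyr::summarise(g = min(diff(time)), .groups = "drop")
  expect_true(all(gaps$g >= cfg$min_gap))
  # determinism under an identical seed
  sch2 <- sample_schedule(design_config(n_persons = 20, n_days = 5, seed = 7))
  expect_identical(sch, sch2)
})

test_that("answered fraction follows the compliance probability", {
  cfg <- design_config(n_persons = 125, n_days = 10, compliance = 1, seed = 1)
  expect_true(all(sample_schedule(cfg)$answered))
  cfg <- design_config(n_persons = 125, n_days = 20, compliance = 0.67,
                       seed = 2)
  sch <- sample_schedule(cfg)          # 10,000 prompts
  se <- sqrt(0.67 * 0.33 / nrow(sch))
  expect_lt(abs(mean(sch$answered) - 0.67), 3 * se)
})

test_that("simulate_person_series matches AR(1) closed forms", {
  set.seed(3)
  # pure white noise: no carry-over
  x <- simulate_person_series(re_vec(), diag(2), 20000)
  r1 <- cor(x[-1, 1], x[-nrow(x), 1])
  expect_lt(abs(r1), 0.02)
  # AR(1) stationary variance: var = 1 / (1 - phi^2)
  x <- simulate_person_series(re_vec(phi_ss = 0.277), diag(2), 100000)
  expect_equal(var(x[, 1]), 1 / (1 - 0.277^2), tolerance = 0.03)
  # stationarity guard
  expect_error(simulate_person_series(re_vec(phi_ss = 1), diag(2), 2),
               "stationar")
})

test_that("empirical covariance of a long simulation solves the Lyapunov equation", {
  set.seed(4)
  re <- re_vec(phi_ss = 0.4, phi_aa = 0.25, phi_as = 0.1, phi_sa = 0.2)
  sw <- matrix(c(1, 0.3, 0.3, 1.2), 2)
  x <- simulate_person_series(re, sw, 100000)
  s_emp <- cov(x)
  phi <- matrix(c(0.4, 0.1, 0.2, 0.25), 2, 2, byrow = TRUE)
  s_theory <- stationary_cov(phi, sw)
  expect_equal(s_emp, s_theory, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("simulate_traits reproduces the demographic margins", {
  truth <- small_truth()
  tr <- simulate_traits(10000, truth, seed = 5)
  p <- tr$persons
  expect_true(all(as.matrix(p[, paste0("adhd", 1:9)]) %in% 1:5))
  expect_lt(abs(mean(p$ses) - 49.09), 3 * 17.58 / sqrt(10000) + 0.5)
  expect_true(all(p$ses >= 16 & p$ses <= 88))
  expect_lt(abs(mean(p$sex) - 101 / 262), 0.02)
  expect_lt(abs(mean(p$origin) - 0.375), 0.02)
})

test_that("zero loadings disconnect items from the factor", {
  truth <- small_truth(lambda_adhd = c(1, rep(0, 8)),
                       item_resid_sd = rep(1, 23))
  tr <- simulate_traits(4000, truth, seed = 6)
  r <- cor(tr$latent$adhd, tr$persons$adhd2)
  expect_lt(abs(r), 0.05)
})

test_that("a single threshold yields binary items with the normal-CDF split", {
  # one cut at 0: P(category 2) = P(propensity > 0) = 0.5 marginally,
  # and Phi(lambda * f / resid_sd ... ) conditionally; check the marginal
  # and the conditional at a fixed factor value.
  truth <- small_truth(thresholds = 0)
  tr <- simulate_traits(20000, truth, seed = 7)
  item <- tr$persons$adhd3                  # lambda = 0.8, resid_sd = 0.8
  expect_true(all(item %in% 1:2))
  expect_lt(abs(mean(item == 2) - 0.5), 0.015)
  f <- tr$latent$adhd
  hi <- f > 0.9 & f < 1.1                   # around f = 1
  p_oracle <- pnorm(0.8 * 1 / 0.8)          # P(lambda f + e > 0 | f = 1)
  expect_lt(abs(mean(item[hi] == 2) - p_oracle), 0.04)
})

test_that("item-factor association grows with the loading", {
  truth <- small_truth(lambda_adhd = c(1, 0.2, 0.6, 1.2, rep(0.8, 5)),
                       item_resid_sd = rep(1, 23))
  tr <- simulate_traits(6000, truth, seed = 8)
  rs <- sapply(paste0("adhd", 2:4), function(j) cor(tr$latent$adhd,
                                                    tr$persons[[j]]))
  expect_true(all(diff(rs) > 0))
})

test_that("simulate_dataset is deterministic and respects score ranges", {
  cfg <- small_config()
  d1 <- simulate_dataset(cfg, small_truth(), seed = 9)
  d2 <- simulate_dataset(cfg, small_truth(), seed = 9)
  expect_identical(d1$ema, d2$ema)
  expect_identical(d1$persons, d2$persons)
  expect_true(all(d1$ema$stress_sum >= 4 & d1$ema$stress_sum <= 20))
  expect_true(all(d1$ema$affect_sum >= 7 & d1$ema$affect_sum <= 35))
  expect_true(all(d1$ema$person_id %in% d1$persons$person_id))
  # items sum to the reported sums
  expect_equal(rowSums(d1$ema[, paste0("s", 1:4)]), as.numeric(d1$ema$stress_sum))
  expect_equal(rowSums(d1$ema[, paste0("a", 1:7)]), as.numeric(d1$ema$affect_sum))
})

test_that("null structural model gives uncorrelated traits and dynamics", {
  truth <- small_truth(
    gamma_adhd_std = stats::setNames(rep(0, 6), names(small_truth()$nu)),
    beta_int_std = stats::setNames(rep(0, 6), names(small_truth()$nu)),
    beta_adhd_std = 0)
  ds <- simulate_dataset(design_config(n_persons = 300, n_days = 6, seed = 1),
                         truth, seed = 10)
  means <- ds$ema |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(m = mean(affect_sum))
  r <- cor(means$m, ds$latent$adhd[means$person_id])
  expect_lt(abs(r), 3 / sqrt(nrow(means)))
})

test_that("dataset round-trips through plain-text serialisation", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(small_config(), small_truth(), seed = 12)
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  ema <- read_ema_csv(paths[["ema"]])
  expect_equal(nrow(ema), nrow(ds$ema))
  expect_equal(ema$stress_sum, ds$ema$stress_sum)
  truth_json <- jsonlite::read_json(paths[["truth"]])
  expect_equal(unlist(truth_json$nu), unlist(ds$truth$nu),
               tolerance = 1e-8, ignore_attr = TRUE)
})
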