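# Equidistant gridding: bin assignment, collision rules, missingness.

rec <- function(t, stress = 10, affect = 14, person_id = 1L) {
  tibble::tibble(person_id = person_id, t = t, stress = stress,
                 affect = affect)
}

test_that("a gap of two grid widths inserts exactly one missing cell", {
  g <- build_grid(rec(c(600, 600 + 480)), delta = 240, origin = 600)
  expect_equal(nrow(g$values), 3)
  expect_true(is.na(g$values$stress[2]))
  expect_equal(sum(is.na(g$values$stress)), 1)
})

test_that("already equidistant records grid without missing cells", {
  g <- build_grid(rec(600 + c(0, 240, 480)), delta = 240, origin = 600)
  expect_equal(nrow(g$values), 3)
  expect_false(anyNA(g$values$stress))
})

test_that("gridding is idempotent and preserves record order", {
  set.seed(1)
  t_in <- 600 + sort(sample(0:50, 12)) * 240        # distinct bins
  vals <- seq_along(t_in)
  g1 <- build_grid(rec(t_in, stress = vals + 4, affect = vals + 7))
  on_grid <- g1$values[!is.na(g1$values$stress), ]
  g2 <- build_grid(tibble::tibble(person_id = 1, t = on_grid$time,
                                  stress = on_grid$stress,
                                  affect = on_grid$affect))
  expect_equal(g2$values, g1$values)
  # order preserved: slot order equals time order of the records
  expect_equal(order(on_grid$stress), seq_len(nrow(on_grid)))
})

test_that("collision rules behave as documented", {
  two <- rec(c(600, 700, 1100))        # first two share bin 0, third bin 2
  e <- build_grid(two, collision = "earliest")
  expect_equal(e$n_dropped, 1)
  expect_equal(e$values$stress[1], 10)
  expect_true(is.na(e$values$stress[2]))

  l <- build_grid(rec(c(600, 700, 1100), stress = c(8, 12, 16)),
                  collision = "latest")
  expect_equal(l$values$stress[1], 12)

  s <- build_grid(rec(c(600, 700, 1100), stress = c(8, 12, 16)),
                  collision = "shift")
  expect_equal(s$n_dropped, 0)
  expect_equal(s$values$stress[1:3], c(8, 12, 16))   # second moved to bin 1

  m <- build_grid(rec(c(600, 700, 1100), stress = c(8, 12, 16)),
                  collision = "mean")
  expect_equal(m$values$stress[1], 10)
})

test_that("build_grid rejects degenerate input", {
  expect_error(build_grid(rec(numeric(0))), "No records")
  expect_error(build_grid(rec(600), delta = -1), "positive")
  expect_error(build_grid(rec(100), origin = 600), "earlier")
})

test_that("missingness_fraction counts missing cells directly", {
  g <- build_grid(rec(600 + c(0, 9) * 240))          # 10 cells, 8 missing
  expect_equal(missingness_fraction(g), 0.8)
  g0 <- build_grid(rec(600 + (0:9) * 240))
  expect_equal(missingness_fraction(g0), 0)
})

test_that("pooled missingness matches a brute-force bin enumeration oracle", {
  cfg <- design_config(n_persons = 30, seed = 13)
  sch <- sample_schedule(cfg)
  ema <- sch[sch$answered, c("person_id", "time")]
  names(ema)[2] <- "t"
  ema$stress <- 10; ema$affect <- 14
  al <- align_ema(ema, delta = 240, origin = 600, collision = "earliest")
  # independent enumeration: occupied bins = distinct floor bins per person
  occ <- 0; tot <- 0
  for (i in unique(ema$person_id)) {
    b <- floor((ema$t[ema$person_id == i] - 600) / 240)
    occ <- occ + length(unique(b))
    tot <- tot + max(b) + 1
  }
  expect_equal(missingness_fraction(al), 1 - occ / tot)
})

test_that("missingness decreases with compliance", {
  set.seed(14)
  cfg <- design_config(n_persons = 40, compliance = 1, seed = 15)
  sch <- sample_schedule(cfg)
  u <- runif(nrow(sch))
  last <- !duplicated(sch$person_id, fromLast = TRUE)
  miss <- sapply(c(0.4, 0.6, 0.8, 1), function(p) {
    keep <- u < p | last                 # nested sets; final prompt kept
    ema <- sch[keep, c("person_id", "time")]
    names(ema)[2] <- "t"
    ema$stress <- 10; ema$affect <- 14
    missingness_fraction(align_ema(ema))
  })
  expect_true(all(diff(miss) <= 0))
})

test_that("compliance_fraction is the answered share", {
  sch <- tibble::tibble(answered = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(compliance_fraction(sch), 0.75)
  expect_equal(compliance_fraction(tibble::tibble(answered = rep(TRUE, 5))), 1)
  expect_equal(compliance_fraction(tibble::tibble(answered = rep(FALSE, 5))), 0)
  expect_error(compliance_fraction(tibble::tibble(answered = logical(0))),
               "no prompts")
  set.seed(16)
  sch <- tibble::tibble(answered = runif(40000) < 0.67)
  expect_lt(abs(compliance_fraction(sch) - 0.67),
            3 * sqrt(0.67 * 0.33 / 40000))
})

test_that("missingness_report summarises per person and pools", {
  ds <- simulate_dataset(small_config(), small_truth(), seed = 17)
  ema <- dplyr::rename(ds$ema, stress = stress_sum, affect = affect_sum)
  al <- align_ema(ema)
  rep <- missingness_report(al)
  expect_equal(rep$n_persons, length(unique(ema$person_id)))
  expect_equal(rep$pooled_missingness,
               sum(rep$per_person$n_missing) / sum(rep$per_person$n_slots))
})
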