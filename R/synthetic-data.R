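# Synthetic EMA study generator.
#
# Emulates a two-week smartphone EMA design: four quasi-random prompts per day
# between 10:00 and 22:00, partial compliance, momentary perceived-stress
# (4 items, sum 4-20) and negative-affect (7 items, sum 7-35) scales, plus a
# person-level questionnaire with 9 ADHD items and 14 internalising items and
# demographic covariates. The latent side follows the same two-level model the
# estimator assumes: a person-specific bivariate lag-1 process within persons,
# and between persons a latent ADHD factor that shifts the person-specific
# means, autoregressive and cross-lagged coefficients, with a latent
# internalising factor regressed on those person-specific dynamics.

#' EMA design configuration
#'
#' @param n_persons number of participants.
#' @param n_days number of study days.
#' @param prompts_per_day prompts issued per day.
#' @param window_start,window_end clock hours delimiting the daily prompt
#'   window (defaults 10 and 22).
#' @param compliance probability that an issued prompt is answered.
#' @param min_gap minimum spacing between consecutive prompts, minutes.
#' @param seed optional integer seed used by [sample_schedule()] and
#'   [simulate_dataset()].
#' @return A `design_config` list.
#' @export
design_config <- function(n_persons = 262, n_days = 14, prompts_per_day = 4,
                          window_start = 10, window_end = 22,
                          compliance = 0.67, min_gap = 30, seed = NULL) {
  stopifnot(n_persons >= 1, n_days >= 1, prompts_per_day >= 1,
            compliance >= 0, compliance <= 1, min_gap >= 0)
  if (window_end <= window_start) {
    abort("`window_end` must be later than `window_start`.")
  }
  window_min <- (window_end - window_start) * 60
  if (prompts_per_day * min_gap >= window_min) {
    abort("Daily window too small for the requested prompts with the minimum gap.")
  }
  structure(
    list(n_persons = as.integer(n_persons), n_days = as.integer(n_days),
         prompts_per_day = as.integer(prompts_per_day),
         window_start = window_start, window_end = window_end,
         compliance = compliance, min_gap = min_gap, seed = seed),
    class = "design_config")
}

#' Generative model parameters
#'
#' Defines the full generative parameter set. Structural coefficients are
#' specified on the standardised scale (the scale on which results are usually
#' reported) together with the marginal scales of each quantity; the
#' unstandardised generating coefficients are derived internally. Defaults
#' describe a young-adult stress/affect EMA study in which ADHD traits moderate
#' stress carry-over and stress-to-affect reactivity and internalising problems
#' load on mean negative affect, stress inertia and ADHD.
#'
#' @param nu population values of the six person-specific dynamic parameters
#'   (means of stress and affect on the sum-score scale; autoregressive and
#'   cross-lagged coefficients). Names: `mu_s`, `mu_a`, `phi_ss`, `phi_aa`,
#'   `phi_as` (lagged affect in the stress equation), `phi_sa` (lagged stress
#'   in the affect equation).
#' @param re_total_sd total between-person SD of each of the six random
#'   effects.
#' @param gamma_adhd_std standardised regressions of each random effect on the
#'   latent ADHD factor.
#' @param gamma_cov_std standardised 6 x 3 matrix of covariate effects
#'   (columns: sex male=1, caregiver origin other=1, childhood SES z-scored) on
#'   the random effects; zero by default (baseline model).
#' @param within_stat_sd stationary within-person SDs of the latent stress and
#'   affect deviations (sum-score units). The within-person innovation
#'   covariance is derived from these, `within_stat_cor` and the population
#'   transition matrix so the implied stationary covariance matches.
#' @param within_stat_cor stationary within-person correlation between the
#'   stress and affect deviations.
#' @param beta_int_std standardised regressions of latent internalising on the
#'   six random effects.
#' @param beta_adhd_std standardised direct effect of latent ADHD on latent
#'   internalising.
#' @param beta_cov_std standardised covariate effects on internalising.
#' @param var_int total variance of the latent internalising factor.
#' @param psi_adhd variance of the latent ADHD factor.
#' @param lambda_adhd,lambda_int factor loadings of the 9 ADHD and the 14
#'   internalising items (first of each fixed at 1, the reference indicator).
#' @param lambda_cross loading of the restless-inside ADHD item on the
#'   internalising factor.
#' @param cross_item name of the item carrying the cross-loading.
#' @param thresholds cut-points on the standardised item-propensity scale
#'   mapping continuous propensities to the 1-5 response categories; strictly
#'   increasing.
#' @param item_resid_sd residual SDs of the item propensities; defaults to the
#'   loading of each item, giving standardised loadings of about 0.71.
#' @param sex_p_male,origin_p_other marginal probabilities of the binary
#'   covariates.
#' @param ses_mean,ses_sd,ses_range moments and truncation range of the raw
#'   childhood-SES score.
#' @return A `true_model` list holding both the user scale parameters and the
#'   derived unstandardised generating coefficients (`gamma_adhd`, `gamma_cov`,
#'   `beta_int`, `beta_adhd`, `beta_cov`, `beta0`, `re_resid_sd`, `sigma_w`,
#'   `sigma_int2`).
#' @export
true_model <- function(
    nu = c(mu_s = 9, mu_a = 12, phi_ss = 0.277, phi_aa = 0.183,
           phi_as = 0.032, phi_sa = 0.115),
    re_total_sd = c(mu_s = 1.5, mu_a = 2.0, phi_ss = 0.2, phi_aa = 0.2,
                    phi_as = 0.2, phi_sa = 0.2),
    gamma_adhd_std = c(mu_s = 0.259, mu_a = 0.359, phi_ss = 0.392,
                       phi_aa = -0.245, phi_as = -0.205, phi_sa = 0.464),
    gamma_cov_std = matrix(0, 6, 3, dimnames = list(re_names(), cov_names())),
    within_stat_sd = c(2, 2), within_stat_cor = 0.3,
    beta_int_std = c(mu_s = 0.102, mu_a = 0.331, phi_ss = 0.191,
                     phi_aa = 0.019, phi_as = 0.019, phi_sa = 0.019),
    beta_adhd_std = 0.426, beta_cov_std = c(0, 0, 0), var_int = 1,
    psi_adhd = 1,
    lambda_adhd = c(1, 0.9, 0.8, 1.1, 0.7, 1.0, 0.85, 0.95, 0.75),
    lambda_int = c(1, 0.9, 0.8, 1.1, 0.7, 1.0, 0.85, 0.95, 0.75, 1.05,
                   0.8, 0.9, 1.0, 0.85),
    lambda_cross = 0.3, cross_item = "adhd5",
    thresholds = c(-1.5, -0.5, 0.5, 1.5),
    item_resid_sd = NULL,
    sex_p_male = 101 / 262, origin_p_other = 0.375,
    ses_mean = 49.09, ses_sd = 17.58, ses_range = c(16, 88)) {

  rn <- re_names()
  nu <- nu[rn]; re_total_sd <- re_total_sd[rn]
  gamma_adhd_std <- gamma_adhd_std[rn]; beta_int_std <- beta_int_std[rn]
  stopifnot(!anyNA(nu), !anyNA(re_total_sd), all(re_total_sd > 0),
            length(lambda_adhd) == 9, length(lambda_int) == 14,
            lambda_adhd[1] == 1, lambda_int[1] == 1,
            all(diff(thresholds) > 0), psi_adhd > 0, var_int > 0)

  # Within-person innovation covariance implied by the target stationary
  # covariance at the population transition matrix.
  phi_pop <- phi_matrix(nu)
  if (spectral_radius(phi_pop) >= 0.95) {
    abort("Population transition matrix violates the stationarity guard.")
  }
  s_stat <- diag(within_stat_sd) %*%
    matrix(c(1, within_stat_cor, within_stat_cor, 1), 2, 2) %*%
    diag(within_stat_sd)
  sigma_w <- s_stat - phi_pop %*% s_stat %*% t(phi_pop)
  if (min(eigen(sigma_w, only.values = TRUE)$values) <= 0) {
    abort("Implied innovation covariance is not positive-definite.")
  }
  dimnames(sigma_w) <- list(c("stress", "affect"), c("stress", "affect"))

  # Covariate marginal covariance (covariates generated independently; SES
  # enters the structural model z-scored).
  cov_var <- c(sex_p_male * (1 - sex_p_male),
               origin_p_other * (1 - origin_p_other), 1)

  # Unstandardised structural coefficients from the standardised inputs.
  gamma_adhd <- gamma_adhd_std * re_total_sd / sqrt(psi_adhd)
  gamma_cov <- gamma_cov_std * (re_total_sd / rep(sqrt(cov_var), each = 6))
  re_resid_var <- re_total_sd^2 - gamma_adhd^2 * psi_adhd -
    as.numeric(gamma_cov^2 %*% cov_var)
  if (any(re_resid_var <= 0)) {
    abort("Standardised effects on a random effect imply a negative residual variance.")
  }
  beta_int <- beta_int_std * sqrt(var_int) / re_total_sd
  beta_adhd <- beta_adhd_std * sqrt(var_int) / sqrt(psi_adhd)
  beta_cov <- beta_cov_std * sqrt(var_int) / sqrt(cov_var)
  explained <- as.numeric(
    (sum(beta_int_std * gamma_adhd_std) + beta_adhd_std)^2 * var_int +
      sum(beta_int_std^2 * var_int * (re_resid_var / re_total_sd^2)) +
      sum(beta_cov_std^2 * var_int) +
      var_int * sum((beta_int_std %*% gamma_cov_std)^2))
  sigma_int2 <- var_int - explained
  if (sigma_int2 <= 0) {
    abort("Structural coefficients imply a negative internalising residual variance.")
  }
  cov_mean <- c(sex_p_male, origin_p_other, 0)
  beta0 <- -sum(beta_int * nu) - sum(beta_cov * cov_mean)

  if (is.null(item_resid_sd)) {
    item_resid_sd <- c(lambda_adhd * sqrt(psi_adhd), lambda_int * sqrt(var_int))
  }
  names(item_resid_sd) <- c(paste0("adhd", 1:9), paste0("int", 1:14))

  structure(list(
    nu = nu, re_total_sd = re_total_sd, re_resid_sd = sqrt(re_resid_var),
    gamma_adhd_std = gamma_adhd_std, gamma_adhd = gamma_adhd,
    gamma_cov_std = gamma_cov_std, gamma_cov = gamma_cov,
    sigma_w = sigma_w, within_stat_sd = within_stat_sd,
    within_stat_cor = within_stat_cor,
    beta_int_std = beta_int_std, beta_int = beta_int,
    beta_adhd_std = beta_adhd_std, beta_adhd = beta_adhd,
    beta_cov_std = beta_cov_std, beta_cov = beta_cov, beta0 = beta0,
    var_int = var_int, sigma_int2 = sigma_int2, psi_adhd = psi_adhd,
    lambda_adhd = lambda_adhd, lambda_int = lambda_int,
    lambda_cross = lambda_cross, cross_item = cross_item,
    thresholds = thresholds, item_resid_sd = item_resid_sd,
    sex_p_male = sex_p_male, origin_p_other = origin_p_other,
    ses_mean = ses_mean, ses_sd = ses_sd, ses_range = ses_range),
    class = "true_model")
}

cov_names <- function() c("sex", "origin", "ses_z")

#' Sample an EMA prompt schedule
#'
#' Draws the prompt times for every person: one uniform draw per consecutive
#' stratum of the daily window (stratified quasi-random scheduling), with the
#' minimum inter-prompt gap enforced by resampling, and independent
#' Bernoulli(compliance) answered flags.
#'
#' @param cfg a [design_config()].
#' @return A tibble with columns `person_id`, `day`, `prompt`, `time`
#'   (minutes from study start, day 1 00:00), `answered`.
#' @export
sample_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "design_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  window <- (cfg$window_end - cfg$window_start) * 60
  k <- cfg$prompts_per_day
  stratum <- window / k

  draw_day <- function() {
    t <- cfg$window_start * 60 + (seq_len(k) - 1) * stratum +
      runif(k, 0, stratum)
    if (k > 1) {
      for (j in 2:k) {
        tries <- 0
        while (t[j] - t[j - 1] < cfg$min_gap && tries < 100) {
          t[j] <- cfg$window_start * 60 + (j - 1) * stratum + runif(1, 0, stratum)
          tries <- tries + 1
        }
        if (t[j] - t[j - 1] < cfg$min_gap) t[j] <- t[j - 1] + cfg$min_gap
      }
    }
    t
  }

  n_prompt <- cfg$n_persons * cfg$n_days * k
  out <- tibble(
    person_id = rep(seq_len(cfg$n_persons), each = cfg$n_days * k),
    day = rep(rep(seq_len(cfg$n_days), each = k), times = cfg$n_persons),
    prompt = rep(seq_len(k), times = cfg$n_persons * cfg$n_days))
  times <- numeric(n_prompt)
  idx <- 1
  for (i in seq_len(cfg$n_persons)) {
    for (d in seq_len(cfg$n_days)) {
      times[idx:(idx + k - 1)] <- (d - 1) * 1440 + draw_day()
      idx <- idx + k
    }
  }
  out$time <- times
  out$answered <- runif(n_prompt) < cfg$compliance
  out
}

#' Simulate one person's latent within-person series
#'
#' Generates the latent (stress, affect) deviations on the equidistant grid:
#' `x_t = Phi x_{t-1} + e_t`, `e_t ~ N(0, sigma_w)`, with the initial state
#' drawn from the stationary distribution.
#'
#' @param re named random-effect vector (see [true_model()] for names); only
#'   the four transition coefficients are used here.
#' @param sigma_w 2 x 2 innovation covariance.
#' @param n_time series length (>= 2).
#' @param seed optional seed.
#' @return An `n_time` x 2 matrix of latent deviations (`stress`, `affect`).
#' @export
simulate_person_series <- function(re, sigma_w, n_time, seed = NULL) {
  stopifnot(n_time >= 2)
  if (!is.null(seed)) set.seed(seed)
  phi <- phi_matrix(re)
  if (spectral_radius(phi) >= 0.95) {
    abort("Person transition matrix violates the stationarity guard (spectral radius >= 0.95).")
  }
  s0 <- stationary_cov(phi, sigma_w)
  x <- matrix(0, n_time, 2, dimnames = list(NULL, c("stress", "affect")))
  x[1, ] <- rmvnorm_chol(1, c(0, 0), s0)
  innov <- rmvnorm_chol(n_time - 1, c(0, 0), sigma_w)
  for (t in 2:n_time) x[t, ] <- phi %*% x[t - 1, ] + innov[t - 1, ]
  x
}

# Categorise continuous propensities into 1..K via thresholds on the
# standardised propensity scale.
categorise <- function(propensity, sd_propensity, thresholds) {
  z <- propensity / sd_propensity
  1L + rowSums(outer(z, thresholds, `>`))
}

#' Simulate person-level traits
#'
#' Draws the latent ADHD factor, the ordinal ADHD questionnaire items and the
#' demographic covariates (sex, caregiver country of origin, childhood SES).
#' The internalising factor and its items depend on each person's realised
#' dynamics and are generated in [simulate_dataset()]; the cross-loading
#' contribution to the restless-inside item is therefore also deferred.
#'
#' @param n_persons number of persons.
#' @param truth a [true_model()].
#' @param seed optional seed.
#' @return A list with `persons` (tibble of items and covariates) and
#'   `latent` (tibble with the latent ADHD scores).
#' @export
simulate_traits <- function(n_persons, truth, seed = NULL) {
  stopifnot(inherits(truth, "true_model"))
  if (!is.null(seed)) set.seed(seed)
  adhd <- rnorm(n_persons, 0, sqrt(truth$psi_adhd))
  items <- gen_items(adhd, truth$lambda_adhd, truth$psi_adhd,
                     truth$item_resid_sd[1:9], truth$thresholds)
  colnames(items) <- paste0("adhd", 1:9)

  sex <- rbinom(n_persons, 1, truth$sex_p_male)
  origin <- rbinom(n_persons, 1, truth$origin_p_other)
  ses <- rnorm(n_persons, truth$ses_mean, truth$ses_sd)
  bad <- ses < truth$ses_range[1] | ses > truth$ses_range[2]
  while (any(bad)) {
    ses[bad] <- rnorm(sum(bad), truth$ses_mean, truth$ses_sd)
    bad <- ses < truth$ses_range[1] | ses > truth$ses_range[2]
  }
  persons <- tibble(person_id = seq_len(n_persons)) |>
    dplyr::bind_cols(as_tibble(items)) |>
    dplyr::mutate(sex = sex, origin = origin, ses = ses)
  list(persons = persons,
       latent = tibble(person_id = seq_len(n_persons), adhd = adhd))
}

# Continuous linear factor propensities discretised by thresholds.
# factor2/lambda2 add an optional second (cross-loading) factor contribution.
gen_items <- function(f, lambda, psi, resid_sd, thresholds,
                      f2 = NULL, lambda2 = NULL, psi2 = 0, item2 = NULL) {
  n <- length(f)
  out <- matrix(0L, n, length(lambda))
  for (j in seq_along(lambda)) {
    lam2 <- if (!is.null(item2) && j == item2) lambda2 else 0
    extra <- if (!is.null(f2)) lam2 * f2 else 0
    prop <- lambda[j] * f + extra + rnorm(n, 0, resid_sd[j])
    sd_prop <- sqrt(lambda[j]^2 * psi + lam2^2 * psi2 + resid_sd[j]^2)
    out[, j] <- categorise(prop, sd_prop, thresholds)
  }
  out
}

# Split a sum score into k items in 1..5 summing exactly to it.
spread_items <- function(total, k) {
  base <- total %/% k
  rem <- total %% k
  vapply(seq_len(k), function(j) base + as.integer(j <= rem), integer(length(total)))
}

#' Simulate a full synthetic EMA dataset
#'
#' Composes [sample_schedule()], the latent dynamics, the momentary sum scores
#' and the person-level questionnaire into one dataset with known generating
#' truth. Answered prompts are deterministically assigned to 4-hour grid slots
#' (the same assignment [build_grid()] performs) and observe the latent state
#' of their slot; sum scores are rounded and clamped to their admissible
#' ranges.
#'
#' @param cfg a [design_config()].
#' @param truth a [true_model()].
#' @param seed integer seed; overrides `cfg$seed` when given.
#' @param delta grid spacing in minutes used for the latent process.
#' @return An `ema_dataset` list: `ema` (answered prompts with items and sum
#'   scores), `schedule` (all prompts), `persons`, `truth`, `latent`
#'   (per-person latent factors and random effects).
#' @export
simulate_dataset <- function(cfg, truth = true_model(), seed = NULL,
                             delta = 240) {
  stopifnot(inherits(cfg, "design_config"), inherits(truth, "true_model"))
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_persons
  cfg_noseed <- cfg
  cfg_noseed$seed <- NULL                    # RNG already seeded once here
  schedule <- sample_schedule(cfg_noseed)

  tr <- simulate_traits(n, truth)
  adhd <- tr$latent$adhd
  covs <- cbind(sex = tr$persons$sex, origin = tr$persons$origin,
                ses_z = as.numeric(scale(tr$persons$ses)))

  # Person-specific random effects; redraw residuals violating the guard.
  re <- matrix(0, n, 6, dimnames = list(NULL, re_names()))
  for (i in seq_len(n)) {
    m <- truth$nu + truth$gamma_adhd * adhd[i] +
      as.numeric(truth$gamma_cov %*% covs[i, ])
    for (try in 1:100) {
      r <- m + rnorm(6, 0, truth$re_resid_sd)
      if (spectral_radius(phi_matrix(r)) < 0.95) break
      if (try == 100) abort("Could not draw a stationary person transition matrix.")
    }
    re[i, ] <- r
  }

  eta <- truth$beta0 + as.numeric(re %*% truth$beta_int) +
    truth$beta_adhd * adhd + as.numeric(covs %*% truth$beta_cov) +
    rnorm(n, 0, sqrt(truth$sigma_int2))

  # Internalising items, and the restless-inside item regenerated with its
  # cross-loading on the internalising factor.
  int_items <- gen_items(eta, truth$lambda_int, truth$var_int,
                         truth$item_resid_sd[10:23], truth$thresholds)
  colnames(int_items) <- paste0("int", 1:14)
  persons <- dplyr::bind_cols(tr$persons[, "person_id"],
                              tr$persons[, paste0("adhd", 1:9)],
                              as_tibble(int_items),
                              tr$persons[, c("sex", "origin", "ses")])
  ci <- match(truth$cross_item, paste0("adhd", 1:9))
  if (!is.na(ci) && truth$lambda_cross != 0) {
    persons[[truth$cross_item]] <- gen_items(
      adhd, truth$lambda_adhd[ci], truth$psi_adhd,
      truth$item_resid_sd[ci], truth$thresholds,
      f2 = eta, lambda2 = truth$lambda_cross, psi2 = truth$var_int,
      item2 = 1L)[, 1]
  }

  origin_min <- grid_origin(cfg)
  ema_list <- vector("list", n)
  for (i in seq_len(n)) {
    sch_i <- schedule[schedule$person_id == i & schedule$answered, ]
    if (nrow(sch_i) == 0) next
    slots <- assign_slots(sch_i$time, delta, origin_min, collision = "shift")
    keep <- !is.na(slots)
    sch_i <- sch_i[keep, ]; slots <- slots[keep]
    n_slot <- max(slots) + 1L
    x <- simulate_person_series(re[i, ], truth$sigma_w, max(n_slot, 2))
    stress <- pmin(pmax(round(re[i, "mu_s"] + x[slots + 1L, "stress"]), 4L), 20L)
    affect <- pmin(pmax(round(re[i, "mu_a"] + x[slots + 1L, "affect"]), 7L), 35L)
    s_items <- spread_items(as.integer(stress), 4L)
    a_items <- spread_items(as.integer(affect), 7L)
    colnames(s_items) <- paste0("s", 1:4)
    colnames(a_items) <- paste0("a", 1:7)
    ema_list[[i]] <- dplyr::bind_cols(
      tibble(person_id = i, t = sch_i$time),
      as_tibble(s_items), as_tibble(a_items),
      tibble(stress_sum = as.integer(stress), affect_sum = as.integer(affect)))
  }
  ema <- dplyr::bind_rows(ema_list)

  latent <- dplyr::bind_cols(
    tibble(person_id = seq_len(n), adhd = adhd, eta_int = eta),
    as_tibble(re))

  structure(list(ema = ema, schedule = schedule, persons = persons,
                 truth = truth, latent = latent, cfg = cfg, delta = delta),
            class = "ema_dataset")
}

#' @export
print.ema_dataset <- function(x, ...) {
  cat("<ema_dataset>\n")
  cat("  persons:", nrow(x$persons), "\n")
  cat("  answered prompts:", nrow(x$ema), "of", nrow(x$schedule), "\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the long-format EMA table and the person-level table as CSV and the
#' generating truth as JSON.
#'
#' @param dataset an `ema_dataset`.
#' @param dir output directory (created if needed).
#' @param start_date calendar date mapped to study day 1 for the ISO-8601
#'   timestamps.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, start_date = as.Date("2021-03-01")) {
  stopifnot(inherits(dataset, "ema_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ema <- dataset$ema
  ema$timestamp <- format(as.POSIXct(start_date, tz = "UTC") + ema$t * 60,
                          "%Y-%m-%dT%H:%M:%SZ")
  paths <- c(ema = file.path(dir, "ema.csv"),
             persons = file.path(dir, "persons.csv"),
             truth = file.path(dir, "truth.json"))
  readr::write_csv(ema, paths["ema"])
  readr::write_csv(dataset$persons, paths["persons"])
  truth <- unclass(dataset$truth)
  truth$sigma_w <- as.vector(truth$sigma_w)
  truth$gamma_cov <- as.vector(truth$gamma_cov)
  truth$gamma_cov_std <- as.vector(truth$gamma_cov_std)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Grid origin in minutes from study start: 10:00 on day 1.
grid_origin <- function(cfg = NULL) {
  start <- if (is.null(cfg)) 10 else cfg$window_start
  start * 60
}
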