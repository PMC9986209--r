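# Posterior summaries: draw-wise standardisation, indirect (mediation)
# effects as within-draw coefficient products, and the results table with
# equal-tailed credible intervals and the CI-excludes-zero significance rule.

re_labels <- function() {
  c(mu_s = "M: Stress", mu_a = "M: Affect",
    phi_ss = "AR: Stress -> Stress", phi_aa = "AR: Affect -> Affect",
    phi_as = "CL: Affect -> Stress", phi_sa = "CL: Stress -> Affect")
}

#' Standardise posterior draws
#'
#' Computes, draw by draw, the standardised counterparts of all structural
#' coefficients so that credible intervals propagate through the
#' standardisation. Within-person coefficients are standardised per person
#' with the person's model-implied stationary within SDs and averaged over
#' persons (this happens during sampling; the averaged values are stored with
#' the draws). Between-level coefficients use the model-implied between-level
#' SDs: `sd(r_k) = sqrt(gamma_k^2 psi + tau2_k + covariate terms)` for a
#' random effect, and the model-implied total SD of the internalising factor
#' for its regression outcomes.
#'
#' @param fit a `dsem_fit` from [run_mcmc()] (baseline or covariates model).
#' @return A tibble of pooled post-burn-in draws: unstandardised coefficients
#'   plus `std_*` columns.
#' @export
standardize_draws <- function(fit) {
  stopifnot(inherits(fit, "dsem_fit"))
  if (fit$model == "none") abort("No between-person structure to standardise.")
  d <- as_tibble(pooled_draws(fit))
  rn <- re_names()
  need <- c(paste0("gamma_", rn), paste0("tau2_", rn), "psi_adhd",
            paste0("beta_", rn), "beta_adhd", "sigma_int2")
  if (!all(need %in% names(d))) abort("Draws are missing variance components.")

  cn <- fit$data_info$cov_names
  cov_cov <- fit$data_info$cov_cov
  n_draw <- nrow(d)
  gam <- as.matrix(d[, paste0("gamma_", rn)])
  tau2 <- as.matrix(d[, paste0("tau2_", rn)])
  psi <- d$psi_adhd
  beta <- as.matrix(d[, paste0("beta_", rn)])
  beta_a <- d$beta_adhd

  # model-implied between-level variance of each random effect
  var_r <- gam^2 * psi + tau2
  if (!is.null(cn)) {
    gcov <- lapply(cn, function(cc) as.matrix(d[, paste0("gamma_", cc, "_", rn)]))
    for (a in seq_along(cn)) for (b in seq_along(cn)) {
      var_r <- var_r + gcov[[a]] * gcov[[b]] * cov_cov[a, b]
    }
  }
  sd_r <- sqrt(var_r)

  # model-implied variance of the internalising factor: substituting the
  # random-effect equations, eta = (beta'gamma + beta_a) A
  # + (beta'Gamma + beta_c') c + beta'u + e.
  bg <- rowSums(beta * gam)
  var_eta <- d$sigma_int2 + beta_a^2 * psi + bg^2 * psi +
    rowSums(beta^2 * tau2) + 2 * beta_a * bg * psi
  if (!is.null(cn)) {
    bcov <- as.matrix(d[, paste0("beta_", cn)])
    bG <- matrix(0, n_draw, length(cn))      # beta' Gamma (per covariate)
    for (a in seq_along(cn)) bG[, a] <- rowSums(beta * gcov[[a]])
    tot <- bG + bcov
    for (a in seq_along(cn)) for (b in seq_along(cn)) {
      var_eta <- var_eta + tot[, a] * tot[, b] * cov_cov[a, b]
    }
  }
  sd_eta <- sqrt(var_eta)

  out <- d
  for (k in seq_along(rn)) {
    out[[paste0("std_nu_", rn[k])]] <- d[[paste0("nu_", rn[k])]] / sd_r[, k]
    out[[paste0("std_gamma_", rn[k])]] <- gam[, k] * sqrt(psi) / sd_r[, k]
    out[[paste0("std_beta_", rn[k])]] <- beta[, k] * sd_r[, k] / sd_eta
  }
  out$std_beta_adhd <- beta_a * sqrt(psi) / sd_eta
  if (!is.null(cn)) {
    for (a in seq_along(cn)) {
      sdc <- sqrt(cov_cov[a, a])
      for (k in seq_along(rn)) {
        out[[paste0("std_gamma_", cn[a], "_", rn[k])]] <-
          gcov[[a]][, k] * sdc / sd_r[, k]
      }
      out[[paste0("std_beta_", cn[a])]] <- bcov[, a] * sdc / sd_eta
    }
  }
  # person-averaged standardised within coefficients are stored as wstd_*
  for (k in th_names()) {
    out[[paste0("std_", k)]] <- d[[paste0("wstd_", k)]]
  }
  out
}

summarise_vec <- function(x, level = 0.95, point = c("median", "mean")) {
  point <- match.arg(point)
  a <- (1 - level) / 2
  q <- quantile(x, c(a, 1 - a), names = FALSE)
  est <- if (point == "median") median(x) else mean(x)
  tibble(estimate = est, sd = sd(x), ci_lower = q[1], ci_upper = q[2],
         significant = q[1] > 0 | q[2] < 0)
}

#' Indirect effects of ADHD on internalising problems
#'
#' For each of the six person-specific dynamic parameters, the mediated path
#' is the within-draw product of the (unstandardised) ADHD-to-random-effect
#' coefficient and the random-effect-to-internalising coefficient; the direct
#' ADHD path is reported alongside. Products are computed draw by draw, never
#' from posterior summaries.
#'
#' @param fit a `dsem_fit`.
#' @param level credible level for the equal-tailed interval.
#' @return A tibble with one row per path: summary statistics plus the
#'   per-draw products in the list column `draws`.
#' @export
indirect_effects <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dsem_fit"))
  d <- as_tibble(pooled_draws(fit))
  rn <- re_names()
  rows <- purrr::map_dfr(rn, function(k) {
    prod <- d[[paste0("gamma_", k)]] * d[[paste0("beta_", k)]]
    dplyr::bind_cols(tibble(label = paste0("via ", re_labels()[[k]])),
                     summarise_vec(prod, level), tibble(draws = list(prod)))
  })
  direct <- dplyr::bind_cols(tibble(label = "direct: ADHD"),
                             summarise_vec(d$beta_adhd, level),
                             tibble(draws = list(d$beta_adhd)))
  dplyr::bind_rows(rows, direct)
}

#' Results table
#'
#' Summarises the posterior into the standard reporting layout: person-mean,
#' autoregressive and cross-lagged blocks (standardised), the effects of
#' ADHD (and covariates) on each random effect, the internalising regression,
#' and the indirect effects (unstandardised). Significance is the
#' CI-excludes-zero rule; no p-values are involved.
#'
#' @param fit a `dsem_fit` (baseline or covariates model).
#' @param level credible level (default 0.95, equal-tailed).
#' @param point `"median"` (default) or `"mean"` posterior point estimate.
#' @return A tibble of result rows: `block`, `label`, `estimate`, `sd`,
#'   `ci_lower`, `ci_upper`, `significant`, `scale`, `note`.
#' @export
make_table <- function(fit, level = 0.95, point = "median") {
  stopifnot(inherits(fit, "dsem_fit"))
  std <- standardize_draws(fit)
  if (nrow(std) == 0) abort("No retained draws.")
  rn <- re_names()
  lab <- re_labels()
  note <- if (fit$status$converged) NA_character_ else "not converged"

  row_of <- function(block, label, col, scale = "standardised") {
    dplyr::bind_cols(tibble(block = block, label = label),
                     summarise_vec(std[[col]], level, point),
                     tibble(scale = scale, note = note))
  }

  rows <- list(
    purrr::map_dfr(c("mu_s", "mu_a"), function(k) {
      row_of("Means (M)", lab[[k]], paste0("std_nu_", k))
    }),
    purrr::map_dfr(c("phi_ss", "phi_aa"), function(k) {
      row_of("Autoregressive effects (AR)", lab[[k]], paste0("std_", k))
    }),
    purrr::map_dfr(c("phi_as", "phi_sa"), function(k) {
      row_of("Cross-lagged effects (CL)", lab[[k]], paste0("std_", k))
    }),
    purrr::map_dfr(rn, function(k) {
      row_of("Effect of ADHD on", lab[[k]], paste0("std_gamma_", k))
    }))

  cn <- fit$data_info$cov_names
  cov_block_names <- c(sex = "Effect of Sex on",
                       origin = "Effect of Primary Caregiver Country of Origin on",
                       ses_z = "Effect of SES on")
  cov_labels <- c(sex = "Sex", origin = "Primary Caregiver Country of Origin",
                  ses_z = "SES")
  if (!is.null(cn)) {
    for (cc in cn) {
      rows <- c(rows, list(purrr::map_dfr(rn, function(k) {
        row_of(cov_block_names[[cc]], lab[[k]],
               paste0("std_gamma_", cc, "_", k))
      })))
    }
  }

  int_rows <- purrr::map_dfr(rn, function(k) {
    row_of("Internalising Problems predicted by", lab[[k]],
           paste0("std_beta_", k))
  })
  int_rows <- dplyr::bind_rows(
    int_rows,
    row_of("Internalising Problems predicted by", "ADHD", "std_beta_adhd"))
  if (!is.null(cn)) {
    int_rows <- dplyr::bind_rows(int_rows, purrr::map_dfr(cn, function(cc) {
      row_of("Internalising Problems predicted by", cov_labels[[cc]],
             paste0("std_beta_", cc))
    }))
  }
  rows <- c(rows, list(int_rows))

  ind <- indirect_effects(fit, level) |>
    dplyr::select(-"draws") |>
    dplyr::mutate(block = "Indirect effects: ADHD to Internalising problems",
                  scale = "unstandardised", note = note, .before = 1) |>
    dplyr::relocate("label", .after = "block")
  dplyr::bind_rows(dplyr::bind_rows(rows), ind)
}

#' @rdname run_mcmc
#' @param x a `dsem_fit`.
#' @param ... passed to [make_table()].
#' @export
tidy.dsem_fit <- function(x, ...) make_table(x, ...)

#' @rdname run_mcmc
#' @export
glance.dsem_fit <- function(x, ...) {
  tibble(model = x$model, n_persons = x$data_info$n_persons,
         n_chains = length(x$draws), iterations = x$status$iterations,
         n_retained = x$status$n_retained,
         converged = x$status$converged,
         max_psr = if (!is.null(x$psr)) max(x$psr) else NA_real_,
         runtime_s = x$runtime)
}

#' Caterpillar plot of the results table
#'
#' @param object a `dsem_fit`.
#' @param ... passed to [make_table()].
#' @return A ggplot object.
#' @export
autoplot.dsem_fit <- function(object, ...) {
  tab <- make_table(object, ...)
  tab$label_f <- factor(paste(tab$block, tab$label, sep = " | "),
                        levels = rev(paste(tab$block, tab$label, sep = " | ")))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$label_f,
                                    colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Posterior estimate (95% CI)", y = NULL,
                  colour = "CI excludes 0")
}
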