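# End-to-end driver: (simulate or read) -> grid -> score -> optional CFA ->
# DSEM -> report, with all artefacts and a reproducibility manifest written
# to an output directory.

#' Read a long-format EMA table
#'
#' @param path CSV with `person_id`, a time column (`t` in minutes or an
#'   ISO-8601 `timestamp`), and either sum scores (`stress_sum`,
#'   `affect_sum`) or the raw items `s1..s4`, `a1..a7`.
#' @return A tibble with `person_id`, `t`, `stress_sum`, `affect_sum`.
#' @export
read_ema_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"t" %in% names(d)) {
    if (!"timestamp" %in% names(d)) abort("Need a `t` or `timestamp` column.")
    ts <- as.POSIXct(d$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%d %H:%M:%S"))
    d$t <- as.numeric(difftime(ts, as.POSIXct(as.Date(min(ts)), tz = "UTC"),
                               units = "mins"))
  }
  if (!"stress_sum" %in% names(d)) {
    scores <- score_scales(d, list(stress_sum = paste0("s", 1:4),
                                   affect_sum = paste0("a", 1:7)))
    d <- dplyr::bind_cols(d, scores)
  }
  d
}

#' Run the full analysis pipeline
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{simulate}{arguments for [design_config()] (a dataset is
#'       simulated), or NULL when `ema_csv`/`persons_csv` are given.}
#'     \item{ema_csv, persons_csv}{input files, used when `simulate` absent.}
#'     \item{delta}{grid spacing in minutes (default 240).}
#'     \item{collision}{grid collision rule (default "shift").}
#'     \item{model}{"baseline" or "covariates".}
#'     \item{cfa}{logical: also fit the trait measurement model (default TRUE).}
#'     \item{mcmc}{arguments for [mcmc_config()].}
#'     \item{seed}{integer master seed.}
#'     \item{out_dir}{output directory.}
#'   }
#' @return Invisibly, a list with the fitted objects, the results table and
#'   the written paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("emadsem_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  delta <- config$delta %||% 240
  collision <- config$collision %||% "shift"
  model <- config$model %||% "baseline"
  t0 <- Sys.time()
  stage_log <- list()
  tick <- function(stage) {
    stage_log[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  if (!is.null(config$simulate)) {
    cfg <- do.call(design_config, config$simulate)
    dataset <- simulate_dataset(cfg, true_model(), seed = seed, delta = delta)
    ema <- dplyr::rename(dataset$ema, stress = "stress_sum",
                         affect = "affect_sum")
    persons <- dataset$persons
    origin <- grid_origin(cfg)
  } else {
    ema_raw <- read_ema_csv(config$ema_csv)
    ema <- dplyr::rename(ema_raw, stress = "stress_sum", affect = "affect_sum")
    persons <- readr::read_csv(config$persons_csv, show_col_types = FALSE)
    dataset <- NULL
    origin <- config$origin %||% 600
  }
  tick("data")

  aligned <- align_ema(ema, delta = delta, origin = origin,
                       collision = collision)
  report <- missingness_report(aligned)
  report$per_person <- NULL
  jsonlite::write_json(report, file.path(out_dir, "missingness.json"),
                       auto_unbox = TRUE, digits = NA)
  tick("grid")

  cfa_fit <- NULL
  if (isTRUE(config$cfa %||% TRUE)) {
    cfa_fit <- fit_cfa(persons, default_trait_spec())
    jsonlite::write_json(
      list(fit = as.list(glance(cfa_fit)),
           omega_adhd = omega(cfa_fit, "adhd"),
           omega_internalising = omega(cfa_fit, "internalising")),
      file.path(out_dir, "cfa.json"), auto_unbox = TRUE, digits = NA)
  }
  tick("cfa")

  mcmc_args <- config$mcmc %||% list()
  mcmc_args$seed <- mcmc_args$seed %||% (seed + 1L)
  fit <- run_mcmc(aligned, persons, model = model,
                  config = do.call(mcmc_config, mcmc_args))
  tick("dsem")

  tab <- make_table(fit)
  readr::write_csv(tab, file.path(out_dir, "results.csv"))
  jsonlite::write_json(
    list(psr = as.list(fit$psr), status = fit$status, seeds = fit$seeds),
    file.path(out_dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  draws <- as_tibble(pooled_draws(fit))
  readr::write_csv(draws, file.path(out_dir, "draws.csv"))
  tick("report")

  manifest <- list(
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("emadsem")),
    stage_seconds = stage_log,
    converged = fit$status$converged)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dataset = dataset, aligned = aligned, cfa = cfa_fit,
                 fit = fit, table = tab, out_dir = out_dir,
                 manifest = manifest))
}
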