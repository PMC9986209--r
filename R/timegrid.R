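# Equidistant time-gridding of irregular EMA records.
#
# The dynamic model requires approximately equidistant measurements; records
# are mapped onto a fixed grid (default spacing 4 h) anchored at 10:00 of
# study day 1, with explicit missing slots inserted wherever no record lands
# (including the overnight slots). With four prompts in a 12-hour day and
# 4-hour bins, two prompts regularly share a bin; the default collision rule
# moves the later record forward into the adjacent slot when that slot is
# free (usually the empty late-evening slot) and drops it otherwise, which is
# the behaviour of interval-binning preprocessors in this field. Alternative
# deterministic rules ("earliest", "latest", "mean") are available; drops are
# reported.

#' Assign record times to grid slots
#'
#' @param t sorted or unsorted numeric times (minutes from study start).
#' @param delta grid spacing in minutes.
#' @param origin grid origin in minutes.
#' @param collision one of `"shift"` (default: a record whose bin is taken is
#'   moved one bin forward if that bin is free, otherwise dropped),
#'   `"earliest"`/`"latest"` (keep one record per bin), or `"none"` (raw floor
#'   bins, possibly duplicated).
#' @return Integer slot per record, in the order of `t`; `NA` marks dropped
#'   records.
#' @export
assign_slots <- function(t, delta, origin, collision = "shift") {
  ord <- order(t)
  bins <- as.integer(floor((t[ord] - origin) / delta))
  if (any(bins < 0)) abort("Record earlier than the grid origin.")
  slots <- rep(NA_integer_, length(bins))
  if (collision == "none") {
    slots <- bins
  } else if (collision == "shift") {
    last <- -1L
    for (k in seq_along(bins)) {
      cand <- max(bins[k], last + 1L)
      if (cand <= bins[k] + 1L) {
        slots[k] <- cand
        last <- cand
      }                                  # else: shift of >1 bin needed; drop
    }
  } else if (collision %in% c("earliest", "latest")) {
    keep <- if (collision == "earliest") !duplicated(bins)
            else !duplicated(bins, fromLast = TRUE)
    slots[keep] <- bins[keep]
  } else {
    abort("Unknown collision rule.")
  }
  out <- rep(NA_integer_, length(t))
  out[ord] <- slots
  out
}

#' Map one person's EMA records onto an equidistant grid
#'
#' Each record is assigned to the bin `floor((t - origin) / delta)` (subject
#' to the collision rule); bins without a record become explicit missing
#' cells, so gaps such as overnight pauses appear as consecutive missing
#' slots.
#'
#' @param records tibble/data.frame with columns `t`, `stress`, `affect` (and
#'   optionally `person_id`) for a single person. `stress`/`affect` are the
#'   sum scores; `stress_sum`/`affect_sum` are accepted as synonyms.
#' @param delta grid spacing in minutes (default 240 = 4 hours).
#' @param origin grid origin in minutes from study start (default 600,
#'   i.e. 10:00 on day 1).
#' @param collision collision rule, see [assign_slots()]; `"mean"`
#'   additionally averages colliding records instead of dropping.
#' @return An `aligned_series` object: a list with `person_id`, `delta`,
#'   `origin`, `values` (tibble `slot`, `time`, `stress`, `affect` covering
#'   every slot from 0 to the last occupied one) and `n_dropped`.
#' @export
build_grid <- function(records, delta = 240, origin = 600,
                       collision = c("shift", "earliest", "latest", "mean")) {
  collision <- match.arg(collision)
  records <- as_tibble(records)
  if (!"stress" %in% names(records) && "stress_sum" %in% names(records)) {
    records$stress <- records$stress_sum
  }
  if (!"affect" %in% names(records) && "affect_sum" %in% names(records)) {
    records$affect <- records$affect_sum
  }
  if (nrow(records) == 0) abort("No records to grid.")
  if (delta <= 0) abort("`delta` must be positive.")
  pid <- if ("person_id" %in% names(records)) records$person_id[1] else NA

  if (collision == "mean") {
    bins <- as.integer(floor((records$t - origin) / delta))
    if (any(bins < 0)) abort("Record earlier than the grid origin.")
    agg <- dplyr::summarise(dplyr::group_by(tibble(slot = bins,
                                                   stress = records$stress,
                                                   affect = records$affect),
                                            .data$slot),
                            stress = mean(.data$stress),
                            affect = mean(.data$affect), .groups = "drop")
    slot_tab <- agg
    n_dropped <- 0L
  } else {
    slots <- assign_slots(records$t, delta, origin, collision)
    keep <- !is.na(slots)
    n_dropped <- sum(!keep)
    slot_tab <- tibble(slot = slots[keep],
                       stress = records$stress[keep],
                       affect = records$affect[keep])
  }
  n_slots <- max(slot_tab$slot) + 1L
  values <- tibble(slot = 0:(n_slots - 1L)) |>
    dplyr::left_join(slot_tab, by = "slot") |>
    dplyr::mutate(time = origin + .data$slot * delta, .after = "slot")
  structure(list(person_id = pid, delta = delta, origin = origin,
                 values = values, n_dropped = n_dropped),
            class = "aligned_series")
}

#' @export
print.aligned_series <- function(x, ...) {
  miss <- mean(is.na(x$values$stress) & is.na(x$values$affect))
  cat("<aligned_series> person", x$person_id, "-", nrow(x$values), "slots,",
      sprintf("%.1f%% missing", 100 * miss),
      if (x$n_dropped > 0) sprintf("(%d records dropped)", x$n_dropped) else "",
      "\n")
  invisible(x)
}

#' Grid an entire EMA table
#'
#' Applies [build_grid()] per person and binds the aligned series into one
#' long tibble.
#'
#' @param ema long EMA table with `person_id`, `t` and sum-score columns.
#' @inheritParams build_grid
#' @return A tibble `person_id`, `slot`, `time`, `stress`, `affect` (class
#'   `aligned_ema`), with the total number of dropped records in attribute
#'   `n_dropped`.
#' @export
align_ema <- function(ema, delta = 240, origin = 600, collision = "shift") {
  series <- lapply(split(as_tibble(ema), ema$person_id), build_grid,
                   delta = delta, origin = origin, collision = collision)
  out <- dplyr::bind_rows(lapply(series, function(s) {
    dplyr::mutate(s$values, person_id = s$person_id, .before = 1)
  }))
  attr(out, "n_dropped") <- sum(vapply(series, `[[`, 0L, "n_dropped"))
  attr(out, "delta") <- delta
  attr(out, "origin") <- origin
  class(out) <- c("aligned_ema", class(out))
  out
}

#' Pooled missingness fraction of aligned series
#'
#' @param aligned an `aligned_ema` tibble, a single `aligned_series`, or a
#'   list of `aligned_series`.
#' @return Proportion of grid cells with no observation, pooled over persons.
#' @export
missingness_fraction <- function(aligned) {
  if (inherits(aligned, "aligned_series")) aligned <- list(aligned)
  if (is.list(aligned) && !is.data.frame(aligned)) {
    aligned <- dplyr::bind_rows(lapply(aligned, `[[`, "values"))
  }
  if (nrow(aligned) == 0) abort("No cells to summarise.")
  mean(is.na(aligned$stress) & is.na(aligned$affect))
}

#' Fraction of issued prompts that were answered
#'
#' @param schedule a schedule tibble with logical column `answered`.
#' @return Proportion answered.
#' @export
compliance_fraction <- function(schedule) {
  if (nrow(schedule) == 0) abort("Schedule contains no prompts.")
  mean(schedule$answered)
}

#' Missingness report
#'
#' @param aligned an `aligned_ema` tibble.
#' @return A list (suitable for JSON serialisation) with pooled and per-person
#'   missingness and dropped-record counts.
#' @export
missingness_report <- function(aligned) {
  per_person <- aligned |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(n_slots = dplyr::n(),
                     n_missing = sum(is.na(.data$stress) & is.na(.data$affect)),
                     .groups = "drop")
  list(pooled_missingness = missingness_fraction(aligned),
       n_persons = nrow(per_person),
       n_cells = sum(per_person$n_slots),
       n_dropped_records = attr(aligned, "n_dropped") %||% 0L,
       per_person = per_person)
}

#' Plot aligned EMA series
#'
#' @param object an `aligned_ema` tibble.
#' @param persons person ids to show (default: first 4).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.aligned_ema <- function(object, persons = NULL, ...) {
  persons <- persons %||% head(unique(object$person_id), 4)
  df <- object |>
    dplyr::filter(.data$person_id %in% persons) |>
    tidyr::pivot_longer(c("stress", "affect"), names_to = "scale",
                        values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 1440, y = .data$score,
                                   colour = .data$scale)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~person_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Study day", y = "Sum score", colour = NULL)
}
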