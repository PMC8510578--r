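new_preference <- function(approach, total, n_larvae) {
  structure(list(value = if (total > 0) approach / total else NA_real_,
                 defined = total > 0,
                 n_decisions = as.integer(total),
                 n_larvae = as.integer(n_larvae)),
            class = "preference_estimate")
}

#' @export
print.preference_estimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("preference %.4f (%d decisions, %d larva%s)\n", x$value,
                x$n_decisions, x$n_larvae, if (x$n_larvae == 1) "" else "e"))
  else
    cat("preference undefined (0 decisions)\n")
  invisible(x)
}

#' Preference index of one animal in one phase
#'
#' The fraction of scored junction choices in which the animal entered the
#' CO2-containing channel: approach / (approach + avoid).  Undefined (and
#' flagged) for an animal that made no decisions in the phase; inactive
#' animals are retained, not dropped.
#'
#' @param record a [larva_record].
#' @param phase one of [PHASES].
#' @return A `preference_estimate` with fields `value`, `defined`,
#'   `n_decisions`, `n_larvae`.
#' @export
larva_preference <- function(record, phase) {
  stopifnot(inherits(record, "larva_record"))
  check_phase(phase)
  new_preference(phase_approach(record, phase), phase_n(record, phase), 1L)
}

#' Decision-weighted population preference
#'
#' Pools all decisions in the group: total approaches divided by total
#' decisions, so animals that made more decisions contribute more heavily.
#' Identical to the ratio formed from [counts_summary] (exact rational
#' equality), and equal to the mean of per-animal preferences only when all
#' animals made the same number of decisions.
#'
#' @param group an [experiment_group].
#' @param phase one of [PHASES].
#' @return A `preference_estimate`.
#' @export
population_preference <- function(group, phase) {
  stopifnot(inherits(group, "experiment_group"))
  check_phase(phase)
  app <- sum(vapply(group$larvae, phase_approach, integer(1), phase))
  tot <- sum(vapply(group$larvae, phase_n, integer(1), phase))
  new_preference(app, tot, length(group$larvae))
}

#' Split one animal's phase into early and late preference estimates
#'
#' Used to test whether expressed preference drifts over the hour-long
#' readout (e.g. extinction during unrewarded testing): compare the first
#' k choices, or the first `time_cut_s` seconds, against the remainder.
#' The two estimates partition the phase, so their decision-weighted
#' recombination equals the full-phase preference.
#'
#' @param record a [larva_record].
#' @param phase one of [PHASES].
#' @param k split after the first `k` choices (rule `k >= 1`).
#' @param time_cut_s alternatively, split at this many seconds from phase
#'   start; requires `time_s` to be present on every decision.
#' @return A list with `preference_estimate` components `early` and `late`.
#' @export
early_late_split <- function(record, phase, k = NULL, time_cut_s = NULL) {
  stopifnot(inherits(record, "larva_record"))
  check_phase(phase)
  if (is.null(k) == is.null(time_cut_s))
    domain_error("give exactly one of k or time_cut_s")
  d <- record$decisions[[phase]]
  if (is.null(d)) d <- decision_frame()
  if (!is.null(k)) {
    if (k < 1) domain_error("k must be >= 1")
    early <- d$outcome[seq_len(min(k, nrow(d)))]
    late <- if (nrow(d) > k) d$outcome[(k + 1):nrow(d)] else character()
  } else {
    if (nrow(d) > 0 && anyNA(d$time_s))
      domain_error("time rule requires time_s on every decision")
    early <- d$outcome[!is.na(d$time_s) & d$time_s < time_cut_s]
    late <- d$outcome[!is.na(d$time_s) & d$time_s >= time_cut_s]
  }
  list(early = new_preference(sum(early == "approach"), length(early), 1L),
       late = new_preference(sum(late == "approach"), length(late), 1L))
}

#' Per-animal (p, n) table for model fitting
#'
#' Flattens groups into one row per animal with its training dose, its
#' preference p in the chosen phase, and its decision count n.  Animals
#' with no decisions in the phase carry no information about the
#' preference distribution and are excluded (the likelihood conditions
#' on n >= 1).
#'
#' @param groups an [experiment_group] or list of them.
#' @param phase phase to score (default `"POST"`).
#' @return `data.frame` with columns `larva_id`, `group`, `dose`, `p`, `n`.
#' @export
preference_data <- function(groups, phase = "POST") {
  if (inherits(groups, "experiment_group")) groups <- list(groups)
  check_phase(phase)
  rows <- lapply(groups, function(grp) {
    n <- vapply(grp$larvae, phase_n, integer(1), phase)
    a <- vapply(grp$larvae, phase_approach, integer(1), phase)
    dose <- vapply(grp$larvae, `[[`, integer(1), "n_cycles")
    ids <- vapply(grp$larvae, `[[`, character(1), "larva_id")
    data.frame(larva_id = ids, group = grp$name, dose = dose,
               p = ifelse(n > 0, a / n, NA_real_), n = n, row.names = NULL)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(larva_id = character(),
                                      group = character(), dose = integer(),
                                      p = numeric(), n = integer())
  out[out$n > 0, , drop = FALSE]
}
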