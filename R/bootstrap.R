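#' Hierarchical bootstrap of decision-weighted preferences
#'
#' Resamples at both levels of the nested design.  Per replicate: draw X
#' animals with replacement from the group's X animals; then, within each
#' drawn animal and independently for each condition (phase), draw its
#' decisions with replacement; recompute the decision-weighted population
#' preference for each condition.  The same drawn animals are used in
#' every condition, respecting the paired design in which each animal
#' contributes both a pre- and a post-training measurement.
#'
#' The replicate standard deviation is the error bar.  When two or more
#' conditions are compared, the p-value is a ranking-consistency score:
#' the fraction of replicates whose condition ranking disagrees with (or
#' ties) the point-estimate ranking.  A value of 0 is reported as
#' `p < 1/B`; it is not evidence of p = 0.
#'
#' Animals with zero decisions in a condition contribute zero draws to the
#' decision-resampling step of that condition but remain in the
#' animal-resampling pool.
#'
#' @param group an [experiment_group].
#' @param phases character vector of one or more conditions (from
#'   [PHASES]) measured on the same animals.
#' @param B number of bootstrap replicates (default 10000).
#' @param seed RNG seed; resampling is reproducible bit-for-bit.
#' @return An object of class `bootstrap_result`: per-condition lists with
#'   `point`, `replicates`, `sd`, and -- when `length(phases) > 1` -- the
#'   comparison `p_value` (with the point-estimate `ranking`).
#' @seealso [animal_bootstrap] for the variant that keeps each animal's
#'   decision sequence intact.
#' @export
hierarchical_bootstrap <- function(group, phases = c("PRE", "POST"),
                                   B = 10000, seed = 1L) {
  bootstrap_engine(group, phases, B, seed, resample_decisions = TRUE)
}

#' Animal-only bootstrap of decision-weighted preferences
#'
#' Identical contract to [hierarchical_bootstrap] except that the decisions
#' of each resampled animal are used as-is, preserving any within-animal
#' correlation between successive choices (the choices are serially
#' anti-correlated in this assay, so this variant typically yields smaller
#' error bars than the hierarchical one).
#'
#' @inheritParams hierarchical_bootstrap
#' @return A `bootstrap_result`; see [hierarchical_bootstrap].
#' @export
animal_bootstrap <- function(group, phases = c("PRE", "POST"),
                             B = 10000, seed = 1L) {
  bootstrap_engine(group, phases, B, seed, resample_decisions = FALSE)
}

bootstrap_engine <- function(group, phases, B, seed, resample_decisions) {
  stopifnot(inherits(group, "experiment_group"))
  for (ph in phases) check_phase(ph)
  if (length(B) != 1 || B < 1) domain_error("B must be a positive integer")
  B <- as.integer(B)
  m <- length(group$larvae)
  if (m == 0) domain_error("empty larva set")

  # per-animal counts: rows = animals, one column set per condition
  n <- sapply(phases, function(ph)
    vapply(group$larvae, phase_n, integer(1), ph))
  a <- sapply(phases, function(ph)
    vapply(group$larvae, phase_approach, integer(1), ph))
  n <- matrix(n, nrow = m); a <- matrix(a, nrow = m)
  phat <- ifelse(n > 0, a / n, 0)

  point <- colSums(a) / colSums(n)
  reps <- matrix(NA_real_, B, length(phases))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(m, m, replace = TRUE)
      if (resample_decisions) {
        # resampling n_i decisions with replacement from a binary list with
        # success fraction p_i is a Binomial(n_i, p_i) draw
        app <- rbinom(length(idx) * length(phases), n[idx, ], phat[idx, ])
        app <- matrix(app, ncol = length(phases))
        reps[b, ] <- colSums(app) / colSums(n[idx, , drop = FALSE])
      } else {
        reps[b, ] <- colSums(a[idx, , drop = FALSE]) /
          colSums(n[idx, , drop = FALSE])
      }
    }
  })

  conditions <- lapply(seq_along(phases), function(j)
    list(phase = phases[j], point = point[j], replicates = reps[, j],
         sd = stats::sd(reps[, j])))
  names(conditions) <- phases

  p_value <- NULL; ranking <- NULL
  if (length(phases) >= 2) {
    ranking <- order(point)
    agree <- vapply(seq_len(B), function(b) {
      r <- reps[b, ]
      !anyNA(r) && !any(duplicated(r)) && identical(order(r), ranking)
    }, logical(1))
    p_value <- sum(!agree) / B   # disagreements and ties count against
  }
  structure(list(conditions = conditions, p_value = p_value,
                 ranking = if (!is.null(ranking)) phases[ranking],
                 B = B, seed = as.integer(seed),
                 hierarchical = resample_decisions),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<%s bootstrap> B = %d, seed = %d\n",
              if (x$hierarchical) "hierarchical" else "animal-only",
              x$B, x$seed))
  for (cond in x$conditions)
    cat(sprintf("  %-9s %.4f (sd %.4f)\n", cond$phase, cond$point, cond$sd))
  if (!is.null(x$p_value))
    cat(sprintf("  ranking %s, p %s\n", paste(x$ranking, collapse = " < "),
                format_p(x$p_value, x$B)))
  invisible(x)
}
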