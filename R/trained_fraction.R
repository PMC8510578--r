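#' Trained fraction of a group with a profile-likelihood interval
#'
#' Holding the component means and variance scale fixed at `theta0` (the
#' global two-Gaussian fit), the likelihood of one dose/protocol group is
#' profiled over the trained mixture weight `f`.  The point estimate `f0`
#' maximizes the profile; the interval is the connected set around `f0`
#' over which the profile log-likelihood stays within 1/2 unit of its
#' maximum, with endpoints located by bracketed root finding and clipped
#' to \[0, 1\].  The log mixture density is linear in `f` inside the log,
#' so the profile is concave and the interval is well defined.  When the
#' two component means coincide the profile is flat and the interval is
#' the whole of \[0, 1\].
#'
#' @param data per-animal `(p, n)` rows for a single group (a `dose`
#'   column, if present, must be constant unless `dose` is supplied to
#'   filter it).
#' @param theta0 list with the fixed remainder parameters `mu_u`, `mu_t`,
#'   `sigma_tilde` (e.g. from a [fit_model] QUANTIZED fit).
#' @param dose optional: restrict `data` to this training dose first.
#' @param tol root tolerance on `f` for the interval endpoints.
#' @return An object of class `trained_fraction_estimate`: `f0`,
#'   `lower`, `upper`, `loglik_max`, `n_larvae`, `theta0`.
#' @export
trained_fraction <- function(data, theta0, dose = NULL, tol = 1e-6) {
  if (!is.null(dose)) data <- data[data$dose == dose, , drop = FALSE]
  data <- data[data$n >= 1, , drop = FALSE]
  if (nrow(data) == 0) domain_error("empty group")
  stopifnot(all(c("mu_u", "mu_t", "sigma_tilde") %in% names(theta0)))

  ldu <- comp_logd(data$p, data$n, theta0$mu_u, theta0$sigma_tilde)
  ldt <- comp_logd(data$p, data$n, theta0$mu_t, theta0$sigma_tilde)
  prof <- function(f) {
    s1 <- log1p(-f) + ldu; s2 <- log(f) + ldt
    m <- pmax(s1, s2)
    sum(m + log(exp(s1 - m) + exp(s2 - m)))
  }
  prof1 <- function(f) if (f <= 0) sum(ldu) else if (f >= 1) sum(ldt) else
    prof(f)

  opt <- stats::optimize(prof1, c(0, 1), maximum = TRUE, tol = tol / 10)
  cand <- c(opt$maximum, 0, 1)
  vals <- vapply(cand, prof1, numeric(1))
  f0 <- cand[which.max(vals)]
  llmax <- max(vals)

  target <- llmax - 0.5
  g <- function(f) prof1(f) - target
  lower <- if (g(0) >= -1e-12) 0 else
    stats::uniroot(g, c(0, f0), tol = tol)$root
  upper <- if (g(1) >= -1e-12) 1 else
    stats::uniroot(g, c(f0, 1), tol = tol)$root

  structure(list(f0 = f0, lower = lower, upper = upper, loglik_max = llmax,
                 n_larvae = nrow(data), theta0 = theta0),
            class = "trained_fraction_estimate")
}

#' @export
print.trained_fraction_estimate <- function(x, ...) {
  cat(sprintf("trained fraction %.3f  [%.3f, %.3f]  (n = %d larvae)\n",
              x$f0, x$lower, x$upper, x$n_larvae))
  invisible(x)
}

#' Per-dose untrained fractions with memoryless-decay overlay
#'
#' Tabulates, per training dose, the untrained mixture weight from a
#' fitted two-Gaussian (QUANTIZED) model together with its
#' profile-likelihood interval, and -- when an ALL_OR_NONE fit is
#' supplied -- the memoryless prediction `lambda^n_c` for comparison.
#'
#' @param quantized_fit a [fit_model] result for the QUANTIZED model.
#' @param data the per-animal data the model was fitted to.
#' @param all_or_none_fit optional [fit_model] result for ALL_OR_NONE.
#' @return data.frame with columns `dose`, `f_untrained`, `lower`,
#'   `upper`, and (when available) `f_untrained_memoryless`.
#' @export
untrained_fraction_curve <- function(quantized_fit, data,
                                     all_or_none_fit = NULL) {
  stopifnot(inherits(quantized_fit, "model_fit"),
            quantized_fit$spec$name == "QUANTIZED")
  doses <- quantized_fit$spec$dose_levels
  th <- quantized_fit$theta
  rows <- lapply(doses, function(d) {
    est <- trained_fraction(data, th, dose = d)
    data.frame(dose = d,
               f_untrained = unname(th$f_u[as.character(d)]),
               lower = 1 - est$upper, upper = 1 - est$lower)
  })
  out <- do.call(rbind, rows)
  if (!is.null(all_or_none_fit)) {
    stopifnot(all_or_none_fit$spec$name == "ALL_OR_NONE")
    out$f_untrained_memoryless <- all_or_none_fit$theta$lambda^out$dose
  }
  out
}
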