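#' The five competing learning models
#'
#' Each model describes the distribution of per-animal post-training
#' preferences `p` (given decision counts `n`) across training doses:
#'
#' * `SHIFTING_MEAN_FIXED_SIGMA`: one Gaussian per dose with free mean and
#'   a single global variance scale (D + 1 parameters).
#' * `GRADED`: one Gaussian per dose with free mean and free sd -- graded
#'   learning (2D parameters).
#' * `QUANTIZED`: a two-Gaussian mixture with fixed component means
#'   (untrained/trained) and a free untrained fraction per dose
#'   (D + 3 parameters).
#' * `THREE_CLUSTER`: a three-Gaussian mixture with ordered fixed means
#'   and two free fractions per dose (2D + 4 parameters).
#' * `ALL_OR_NONE`: the quantized mixture with the untrained fraction
#'   constrained to the memoryless decay `lambda^n_c` (4 parameters).
#'
#' At the study's 8 dose levels the parameter counts are 9, 16, 11, 20,
#' and 4 respectively.
#'
#' @param name one of the model names above.
#' @param dose_levels ordered vector of the training doses present.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = MODEL_NAMES, dose_levels) {
  name <- match.arg(name)
  dose_levels <- sort(unique(as.integer(dose_levels)))
  if (!length(dose_levels)) domain_error("at least one dose level required")
  structure(list(name = name, dose_levels = dose_levels),
            class = "model_spec")
}

#' @rdname model_spec
#' @format `MODEL_NAMES` is the character vector of the five model names.
#' @export
MODEL_NAMES <- c("SHIFTING_MEAN_FIXED_SIGMA", "GRADED", "QUANTIZED",
                 "THREE_CLUSTER", "ALL_OR_NONE")

#' Number of free parameters of a model
#'
#' A pure function of the model name and the number of dose levels.
#'
#' @param spec a [model_spec].
#' @return Integer parameter count.
#' @export
n_params <- function(spec) {
  D <- length(spec$dose_levels)
  switch(spec$name,
         SHIFTING_MEAN_FIXED_SIGMA = D + 1L,
         GRADED = 2L * D,
         QUANTIZED = D + 3L,
         THREE_CLUSTER = 2L * D + 4L,
         ALL_OR_NONE = 4L)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s> %d dose level(s), k = %d\n", x$name,
              length(x$dose_levels), n_params(x)))
  invisible(x)
}

#' Gaussian probability density
#'
#' The component density of every model, untruncated: preferences live in
#' \[0, 1\] but the density is the full normal (no truncation terms enter
#' the likelihood or the parameter counts).
#'
#' @param x evaluation point(s).
#' @param mu mean.
#' @param sigma standard deviation, `> 0`.
#' @return Density value(s).
#' @export
gaussian_density <- function(x, mu, sigma) {
  if (any(sigma <= 0)) domain_error("sigma must be > 0")
  stats::dnorm(x, mu, sigma)
}

#' Variance of a per-animal preference under correlated counting noise
#'
#' If an animal makes `n` choices with marginal approach probability
#' `p_bar`, independent choices give binomial variance `p_bar(1-p_bar)/n`
#' for the mean.  Successive choices in this assay are anti-correlated, so
#' the variance is scaled by a global factor `sigma_tilde^2` (typically
#' < 1).  The result is floored at `floor` so that degenerate proposals
#' (`p_bar` of 0 or 1) keep the density finite during optimization.
#'
#' @param p_bar mean probability, in \[0, 1\].
#' @param n decision count, `>= 1` (animals with no decisions are excluded
#'   upstream).
#' @param sigma_tilde variance scale, `> 0`.
#' @param floor lower bound on the returned variance.
#' @return Variance of the observed preference.
#' @export
variance_model <- function(p_bar, n, sigma_tilde, floor = 1e-6) {
  if (any(p_bar < 0 | p_bar > 1)) domain_error("p_bar must lie in [0, 1]")
  if (any(n < 1)) domain_error("n must be >= 1")
  if (any(sigma_tilde <= 0)) domain_error("sigma_tilde must be > 0")
  pmax(sigma_tilde^2 * p_bar * (1 - p_bar) / n, floor)
}

# log density of observations (p, n) under one mixture component
comp_logd <- function(p, n, mu, sigma_tilde) {
  stats::dnorm(p, mu, sqrt(variance_model(mu, n, sigma_tilde)), log = TRUE)
}

# row-wise log(sum(w * exp(ld))) for a matrix of component log densities
log_mix <- function(logw, ld) {
  # ld: n x K, logw: n x K (or K); returns length-n vector
  if (is.null(dim(logw))) logw <- matrix(logw, nrow(ld), ncol(ld), byrow = TRUE)
  s <- logw + ld
  m <- s[, 1]
  for (k in 2:ncol(s)) m <- pmax(m, s[, k])
  acc <- exp(s[, 1] - m)
  for (k in 2:ncol(s)) acc <- acc + exp(s[, k] - m)
  m + log(acc)
}

check_theta <- function(spec, theta) {
  tol <- 1e-9
  inrange <- function(x) all(is.finite(x)) && all(x >= -tol & x <= 1 + tol)
  ok <- switch(spec$name,
    ALL_OR_NONE = inrange(c(theta$mu_u, theta$mu_t, theta$lambda)) &&
      theta$sigma_tilde > 0,
    QUANTIZED = inrange(c(theta$mu_u, theta$mu_t, theta$f_u)) &&
      theta$sigma_tilde > 0 && length(theta$f_u) == length(spec$dose_levels),
    SHIFTING_MEAN_FIXED_SIGMA = inrange(theta$mu) && theta$sigma_tilde > 0 &&
      length(theta$mu) == length(spec$dose_levels),
    GRADED = inrange(theta$mu) && all(theta$sigma > 0) &&
      length(theta$mu) == length(spec$dose_levels) &&
      length(theta$sigma) == length(spec$dose_levels),
    THREE_CLUSTER = inrange(c(theta$mu1, theta$mu2, theta$mu3, theta$f1,
                              theta$f2)) &&
      theta$sigma_tilde > 0 && all(theta$f1 + theta$f2 <= 1 + tol) &&
      length(theta$f1) == length(spec$dose_levels) &&
      length(theta$f2) == length(spec$dose_levels))
  if (!isTRUE(ok)) domain_error("theta violates the %s invariants", spec$name)
  invisible(TRUE)
}

# core log-likelihood; assumes theta already valid and data has n >= 1
loglik_core <- function(data, spec, theta) {
  doseix <- match(data$dose, spec$dose_levels)
  p <- data$p; n <- data$n
  switch(spec$name,
    ALL_OR_NONE = {
      fu <- theta$lambda^data$dose
      ld <- cbind(comp_logd(p, n, theta$mu_u, theta$sigma_tilde),
                  comp_logd(p, n, theta$mu_t, theta$sigma_tilde))
      sum(log_mix(cbind(log(fu), log1p(-fu)), ld))
    },
    QUANTIZED = {
      fu <- unname(theta$f_u[doseix])
      ld <- cbind(comp_logd(p, n, theta$mu_u, theta$sigma_tilde),
                  comp_logd(p, n, theta$mu_t, theta$sigma_tilde))
      sum(log_mix(cbind(log(fu), log1p(-fu)), ld))
    },
    SHIFTING_MEAN_FIXED_SIGMA = {
      mu <- unname(theta$mu[doseix])
      sum(stats::dnorm(p, mu,
                       sqrt(variance_model(mu, n, theta$sigma_tilde)),
                       log = TRUE))
    },
    GRADED = {
      mu <- unname(theta$mu[doseix])
      sg <- unname(theta$sigma[doseix])
      sum(stats::dnorm(p, mu, sqrt(pmax(sg^2 / n, 1e-6)), log = TRUE))
    },
    THREE_CLUSTER = {
      f1 <- unname(theta$f1[doseix]); f2 <- unname(theta$f2[doseix])
      f3 <- pmax(1 - f1 - f2, 0)
      ld <- cbind(comp_logd(p, n, theta$mu1, theta$sigma_tilde),
                  comp_logd(p, n, theta$mu2, theta$sigma_tilde),
                  comp_logd(p, n, theta$mu3, theta$sigma_tilde))
      sum(log_mix(log(cbind(f1, f2, f3)), ld))
    })
}

#' Log-likelihood of per-animal preference data under a model
#'
#' The sum over animals of the log mixture density of the observed
#' preference, given the animal's decision count and training dose.
#'
#' @param data data.frame with columns `dose`, `p`, `n` (one animal per
#'   row, `n >= 1`); see [preference_data].
#' @param spec a [model_spec] whose `dose_levels` cover the doses present.
#' @param theta named parameter list for the model variant (see
#'   [model_spec]); invariant violations raise a domain error.
#' @return The log-likelihood (finite real).
#' @export
log_likelihood <- function(data, spec, theta) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(data$n < 1)) domain_error("animals with n = 0 must be excluded")
  if (!all(data$dose %in% spec$dose_levels))
    domain_error("data contains doses outside spec$dose_levels")
  check_theta(spec, theta)
  loglik_core(data, spec, theta)
}

# ---- parameter packing (unconstrained optimizer scale) ---------------------
# probabilities/fractions -> logit, sd-like scales -> log; three-cluster
# means ordered via stick-breaking, fractions via multinomial logit.

pack_theta <- function(spec, theta) {
  lg <- function(p) logit(pclamp(p))
  switch(spec$name,
    ALL_OR_NONE = c(lg(theta$mu_u), lg(theta$mu_t), log(theta$sigma_tilde),
                    lg(theta$lambda)),
    QUANTIZED = c(lg(theta$mu_u), lg(theta$mu_t), log(theta$sigma_tilde),
                  lg(theta$f_u)),
    SHIFTING_MEAN_FIXED_SIGMA = c(lg(theta$mu), log(theta$sigma_tilde)),
    GRADED = c(lg(theta$mu), log(pmax(theta$sigma, 1e-6))),
    THREE_CLUSTER = {
      m1 <- theta$mu1; m2 <- theta$mu2; m3 <- theta$mu3
      f1 <- pclamp(theta$f1, 1e-9); f2 <- pclamp(theta$f2, 1e-9)
      f3 <- pmax(1 - f1 - f2, 1e-9)
      c(lg(m1), lg((m2 - m1) / max(1 - m1, 1e-9)),
        lg((m3 - m2) / max(1 - m2, 1e-9)), log(theta$sigma_tilde),
        log(f1 / f3), log(f2 / f3))
    })
}

unpack_theta <- function(spec, par) {
  D <- length(spec$dose_levels)
  nm <- as.character(spec$dose_levels)
  switch(spec$name,
    ALL_OR_NONE = list(mu_u = invlogit(par[1]), mu_t = invlogit(par[2]),
                       sigma_tilde = exp(par[3]), lambda = invlogit(par[4])),
    QUANTIZED = list(mu_u = invlogit(par[1]), mu_t = invlogit(par[2]),
                     sigma_tilde = exp(par[3]),
                     f_u = setNames(invlogit(par[4:(3 + D)]), nm)),
    SHIFTING_MEAN_FIXED_SIGMA = list(
      mu = setNames(invlogit(par[1:D]), nm), sigma_tilde = exp(par[D + 1])),
    GRADED = list(mu = setNames(invlogit(par[1:D]), nm),
                  sigma = setNames(exp(par[(D + 1):(2 * D)]), nm)),
    THREE_CLUSTER = {
      m1 <- invlogit(par[1])
      m2 <- m1 + (1 - m1) * invlogit(par[2])
      m3 <- m2 + (1 - m2) * invlogit(par[3])
      a <- par[5:(4 + D)]; b <- par[(5 + D):(4 + 2 * D)]
      den <- 1 + exp(a) + exp(b)
      list(mu1 = m1, mu2 = m2, mu3 = m3, sigma_tilde = exp(par[4]),
           f1 = setNames(exp(a) / den, nm), f2 = setNames(exp(b) / den, nm))
    })
}

# method-of-moments style start: split animals at preference 0.4
heuristic_start <- function(spec, data) {
  lo <- data$p[data$p < 0.4]; hi <- data$p[data$p >= 0.4]
  mu_u <- if (length(lo)) mean(lo) else 0.27
  mu_t <- if (length(hi)) mean(hi) else 0.52
  fu <- vapply(spec$dose_levels, function(d) {
    pd <- data$p[data$dose == d]
    if (length(pd)) mean(pd < 0.4) else 0.5
  }, numeric(1))
  names(fu) <- as.character(spec$dose_levels)
  pos <- spec$dose_levels > 0
  lambda <- if (any(pos))
    mean(pclamp(fu[pos])^(1 / spec$dose_levels[pos])) else 0.5
  perdose <- function(fun, fallback) {
    v <- vapply(spec$dose_levels, function(d) {
      pd <- data$p[data$dose == d]; nd <- data$n[data$dose == d]
      if (length(pd)) fun(pd, nd) else fallback
    }, numeric(1))
    setNames(v, as.character(spec$dose_levels))
  }
  switch(spec$name,
    ALL_OR_NONE = list(mu_u = mu_u, mu_t = mu_t, sigma_tilde = 0.8,
                       lambda = lambda),
    QUANTIZED = list(mu_u = mu_u, mu_t = mu_t, sigma_tilde = 0.8, f_u = fu),
    SHIFTING_MEAN_FIXED_SIGMA = list(
      mu = perdose(function(p, n) sum(p * n) / sum(n), 0.4),
      sigma_tilde = 0.8),
    GRADED = list(
      mu = perdose(function(p, n) sum(p * n) / sum(n), 0.4),
      sigma = perdose(function(p, n) {
        m <- sum(p * n) / sum(n)
        max(sqrt(mean(n * (p - m)^2)), 0.02)
      }, 0.1)),
    THREE_CLUSTER = {
      ms <- sort(c(mu_u, (mu_u + mu_t) / 2, mu_t))
      list(mu1 = ms[1], mu2 = ms[2], mu3 = ms[3], sigma_tilde = 0.8,
           f1 = fu, f2 = pmin(1 - fu, 0.5) / 2)
    })
}

random_start <- function(spec, data) {
  D <- length(spec$dose_levels)
  nm <- as.character(spec$dose_levels)
  rmu <- function(k) runif(k, 0.05, 0.95)
  rst <- function() exp(runif(1, log(0.4), log(1.5)))
  switch(spec$name,
    ALL_OR_NONE = list(mu_u = rmu(1), mu_t = rmu(1), sigma_tilde = rst(),
                       lambda = runif(1, 0.05, 0.95)),
    QUANTIZED = list(mu_u = rmu(1), mu_t = rmu(1), sigma_tilde = rst(),
                     f_u = setNames(runif(D, 0.05, 0.95), nm)),
    SHIFTING_MEAN_FIXED_SIGMA = list(mu = setNames(rmu(D), nm),
                                     sigma_tilde = rst()),
    GRADED = list(mu = setNames(rmu(D), nm),
                  sigma = setNames(exp(runif(D, log(0.02), log(0.5))), nm)),
    THREE_CLUSTER = {
      ms <- sort(rmu(3))
      f <- matrix(runif(2 * D, 0.05, 0.45), nrow = D)
      list(mu1 = ms[1], mu2 = ms[2], mu3 = ms[3], sigma_tilde = rst(),
           f1 = setNames(f[, 1], nm), f2 = setNames(f[, 2], nm))
    })
}

#' Fit a learning model by maximum likelihood
#'
#' Box constraints are handled by transforming all parameters to an
#' unconstrained scale (logit for probabilities and fractions, log for
#' scale parameters; the three-cluster means are ordered by
#' stick-breaking, removing label switching).  The likelihood is then
#' maximized from multiple starts -- one method-of-moments heuristic, any
#' caller-supplied `extra_starts`, and `n_starts` random starts from a
#' seeded stream -- and the best converged optimum is returned.  Among
#' optima of equal likelihood the one with the smallest leading mean is
#' kept, so refits with the same seed are identical.
#'
#' @param data per-animal `(dose, p, n)` data.frame (see
#'   [preference_data]); at least 2 animals with `n >= 1`.
#' @param spec a [model_spec].
#' @param n_starts number of random multi-starts (default 20).
#' @param seed RNG seed for the random starts.
#' @param extra_starts optional list of theta lists used as additional
#'   starts (e.g. a fitted nested model mapped into this model's
#'   parameter space).
#' @return An object of class `model_fit`: `spec`, `theta`, `loglik`,
#'   `k`, `n_obs`, `aic`, `bic`, and an optimizer trace summary
#'   (`n_starts`, `n_converged`).
#' @export
fit_model <- function(data, spec, n_starts = 20, seed = 1L,
                      extra_starts = list()) {
  stopifnot(inherits(spec, "model_spec"))
  data <- data[data$n >= 1, , drop = FALSE]
  if (nrow(data) < 2) domain_error("need at least 2 animals with n >= 1")
  if (!all(data$dose %in% spec$dose_levels))
    domain_error("data contains doses outside spec$dose_levels")

  nll <- function(par) {
    v <- tryCatch(-loglik_core(data, spec, unpack_theta(spec, par)),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- c(list(pack_theta(spec, heuristic_start(spec, data))),
              lapply(extra_starts, pack_theta, spec = spec),
              with_seed(seed, lapply(seq_len(n_starts), function(i)
                pack_theta(spec, random_start(spec, data)))))

  fits <- lapply(starts, function(par0) {
    tryCatch(stats::optim(par0, nll, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-10)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    ll_stop("larvalearn_fit_error", "no start converged for %s", spec$name)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- min(vals)
  cand <- fits[vals <= best + 1e-8]
  # deterministic tie-break: smallest leading mean, then lexicographic
  lead <- vapply(cand, function(f) unpack_theta(spec, f$par)[[1]][1],
                 numeric(1))
  cand <- cand[order(lead, vapply(cand, function(f)
    paste(sprintf("%.10f", f$par), collapse = ","), character(1)))]
  sel <- cand[[1]]

  theta <- unpack_theta(spec, sel$par)
  ll <- -sel$value
  k <- n_params(spec)
  n_obs <- nrow(data)
  structure(list(spec = spec, theta = theta, loglik = ll, k = k,
                 n_obs = n_obs, aic = 2 * k - 2 * ll,
                 bic = k * log(n_obs) - 2 * ll,
                 n_starts = length(starts),
                 n_converged = sum(vapply(fits, `[[`, integer(1),
                                          "convergence") == 0L),
                 seed = as.integer(seed)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit %s> logLik %.3f  k %d  n %d  AIC %.2f  BIC %.2f\n",
              x$spec$name, x$loglik, x$k, x$n_obs, x$aic, x$bic))
  invisible(x)
}

# map a fitted model into a richer model's parameter space (nesting seeds)
nested_seed <- function(fit, target) {
  th <- fit$theta
  switch(paste(fit$spec$name, target, sep = "->"),
    "ALL_OR_NONE->QUANTIZED" = list(
      mu_u = th$mu_u, mu_t = th$mu_t, sigma_tilde = th$sigma_tilde,
      f_u = setNames(th$lambda^fit$spec$dose_levels,
                     as.character(fit$spec$dose_levels))),
    "QUANTIZED->THREE_CLUSTER" = {
      eps <- 1e-9
      ms <- sort(c(th$mu_u, th$mu_t))
      swapped <- th$mu_u > th$mu_t
      w1 <- if (swapped) 1 - th$f_u else th$f_u
      if (ms[2] - ms[1] < 1e-6) ms[2] <- min(ms[1] + 1e-4, 1 - 1e-6)
      list(mu1 = ms[1], mu2 = ms[2],
           mu3 = min(ms[2] + 0.05, 1 - 1e-6),
           sigma_tilde = th$sigma_tilde,
           f1 = w1 * (1 - 2 * eps), f2 = (1 - w1) * (1 - 2 * eps))
    },
    "SHIFTING_MEAN_FIXED_SIGMA->GRADED" = list(
      mu = th$mu,
      sigma = pmax(th$sigma_tilde * sqrt(th$mu * (1 - th$mu)), 1e-4)),
    NULL)
}

#' Fit and compare learning models
#'
#' Fits each requested model and tabulates log-likelihood, AIC, and BIC
#' differences relative to the best model under each criterion.  Models
#' are fitted in nesting order and each richer model receives the fitted
#' constrained model as an extra start, so the nesting inequalities
#' (all-or-none <= quantized <= three-cluster, fixed-sigma shifting mean
#' <= graded, in maximized log-likelihood) hold by construction.
#'
#' @param data per-animal `(dose, p, n)` data.frame.
#' @param models character vector of model names (default all five).
#' @param n_starts,seed passed to [fit_model].
#' @return A `model_comparison`: data.frame with one row per model
#'   (`model`, `k`, `loglik`, `delta_logP`, `aic`, `delta_aic`, `bic`,
#'   `delta_bic`, `error`) with the fit objects in
#'   `attr(, "fits")`.  Failed fits are flagged per row, not fatal.
#' @export
compare_models <- function(data, models = MODEL_NAMES, n_starts = 20,
                           seed = 1L) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  if (length(models) < 1) domain_error("at least one model required")
  doses <- sort(unique(data$dose))
  order_all <- c("ALL_OR_NONE", "QUANTIZED", "THREE_CLUSTER",
                 "SHIFTING_MEAN_FIXED_SIGMA", "GRADED")
  fit_order <- intersect(order_all, models)
  fits <- list(); errors <- list()
  for (nm in fit_order) {
    parent <- switch(nm, QUANTIZED = "ALL_OR_NONE",
                     THREE_CLUSTER = "QUANTIZED",
                     GRADED = "SHIFTING_MEAN_FIXED_SIGMA", NULL)
    extra <- list()
    if (!is.null(parent) && !is.null(fits[[parent]])) {
      th <- nested_seed(fits[[parent]], nm)
      if (!is.null(th)) extra <- list(th)
    }
    res <- tryCatch(fit_model(data, model_spec(nm, doses),
                              n_starts = n_starts, seed = seed,
                              extra_starts = extra),
                    error = function(e) e)
    if (inherits(res, "error")) errors[[nm]] <- conditionMessage(res)
    else fits[[nm]] <- res
  }
  get_num <- function(nm, field)
    if (!is.null(fits[[nm]])) fits[[nm]][[field]] else NA_real_
  tab <- data.frame(
    model = models,
    k = vapply(models, function(nm)
      n_params(model_spec(nm, doses)), integer(1)),
    loglik = vapply(models, get_num, numeric(1), "loglik"),
    aic = vapply(models, get_num, numeric(1), "aic"),
    bic = vapply(models, get_num, numeric(1), "bic"),
    row.names = NULL)
  tab$delta_logP <- tab$loglik - max(tab$loglik, na.rm = TRUE)
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  tab$delta_bic <- tab$bic - min(tab$bic, na.rm = TRUE)
  tab$error <- vapply(models, function(nm)
    if (!is.null(errors[[nm]])) errors[[nm]] else "", character(1))
  tab <- tab[, c("model", "k", "loglik", "delta_logP", "aic", "delta_aic",
                 "bic", "delta_bic", "error")]
  structure(tab, fits = fits, class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, ...) {
  y <- as.data.frame(x)
  y$loglik <- round(y$loglik, 2); y$delta_logP <- round(y$delta_logP, 2)
  y$aic <- round(y$aic, 2); y$delta_aic <- round(y$delta_aic, 2)
  y$bic <- round(y$bic, 2); y$delta_bic <- round(y$delta_bic, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
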