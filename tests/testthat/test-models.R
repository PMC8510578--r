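study_doses <- c(0, 1, 2, 3, 4, 5, 10, 20)

test_that("component density and variance model evaluate in closed form", {
  expect_equal(gaussian_density(0, 0, 1), 0.3989423, tolerance = 1e-6)
  expect_equal(gaussian_density(0.3, 0.3, 0.05), 1 / sqrt(2 * pi * 0.05^2))
  expect_equal(gaussian_density(0.4, 0.3, 0.1), gaussian_density(0.2, 0.3, 0.1))
  expect_error(gaussian_density(0, 0, 0), class = "larvalearn_domain_error")

  expect_equal(variance_model(0.5, 10, 1), 0.025)
  expect_equal(variance_model(0.5, 10, 0.8), 0.016)
  expect_equal(variance_model(0, 10, 1), 1e-6)   # floored at the boundary
  expect_error(variance_model(0.5, 0, 1), class = "larvalearn_domain_error")
})

test_that("parameter counts match the published model table at 8 doses", {
  ks <- vapply(MODEL_NAMES, function(nm)
    n_params(model_spec(nm, study_doses)), integer(1))
  expect_equal(unname(ks[c("SHIFTING_MEAN_FIXED_SIGMA", "GRADED", "QUANTIZED",
                           "THREE_CLUSTER", "ALL_OR_NONE")]),
               c(9L, 16L, 11L, 20L, 4L))
})

test_that("mixture log-likelihood collapses to the Gaussian peak value", {
  d <- data.frame(dose = 0, p = 0.5, n = 10)
  spec <- model_spec("QUANTIZED", 0)
  th <- list(mu_u = 0.5, mu_t = 0.5, sigma_tilde = 1,
             f_u = c("0" = 0.5))
  # both components sit on the observation: log of N(0, sd = sqrt(0.025))
  expect_equal(log_likelihood(d, spec, th),
               log(1 / sqrt(2 * pi * 0.025)), tolerance = 1e-6)
  expect_equal(log_likelihood(d, spec, th), 0.92548, tolerance = 1e-4)
})

test_that("mixture degenerates to a single Gaussian when one weight is 1", {
  set.seed(9); d <- data.frame(dose = 0, p = runif(30, 0, 1),
                               n = sample(10:40, 30, TRUE))
  spec <- model_spec("QUANTIZED", 0)
  th <- list(mu_u = 0.27, mu_t = 0.52, sigma_tilde = 0.9, f_u = c("0" = 1))
  single <- sum(dnorm(d$p, 0.27,
                      sqrt(pmax(0.9^2 * 0.27 * 0.73 / d$n, 1e-6)),
                      log = TRUE))
  expect_equal(log_likelihood(d, spec, th), single, tolerance = 1e-10)
})

test_that("the exponential-fraction model is the constrained quantized model", {
  set.seed(10)
  d <- data.frame(dose = rep(study_doses, each = 6),
                  p = runif(48), n = sample(10:40, 48, TRUE))
  aon <- model_spec("ALL_OR_NONE", study_doses)
  qz <- model_spec("QUANTIZED", study_doses)
  for (lambda in c(0.3, 0.6, 0.9)) {
    th_a <- list(mu_u = 0.27, mu_t = 0.52, sigma_tilde = 0.85,
                 lambda = lambda)
    th_q <- list(mu_u = 0.27, mu_t = 0.52, sigma_tilde = 0.85,
                 f_u = setNames(lambda^study_doses,
                                as.character(study_doses)))
    expect_equal(log_likelihood(d, aon, th_a), log_likelihood(d, qz, th_q),
                 tolerance = 1e-12)
  }
})

test_that("invariant-violating parameters raise domain errors", {
  d <- data.frame(dose = 0, p = 0.5, n = 10)
  spec <- model_spec("QUANTIZED", 0)
  expect_error(log_likelihood(d, spec,
                              list(mu_u = 1.3, mu_t = 0.5, sigma_tilde = 1,
                                   f_u = c("0" = 0.5))),
               class = "larvalearn_domain_error")
  expect_error(log_likelihood(d, spec,
                              list(mu_u = 0.3, mu_t = 0.5, sigma_tilde = -1,
                                   f_u = c("0" = 0.5))),
               class = "larvalearn_domain_error")
  expect_error(log_likelihood(data.frame(dose = 0, p = 0.5, n = 0), spec,
                              list(mu_u = 0.3, mu_t = 0.5, sigma_tilde = 1,
                                   f_u = c("0" = 0.5))),
               class = "larvalearn_domain_error")
})

test_that("fitting is deterministic under a fixed seed", {
  d <- sim_pref_data(33)
  spec <- model_spec("ALL_OR_NONE", unique(d$dose))
  f1 <- fit_model(d, spec, n_starts = 5, seed = 2)
  f2 <- fit_model(d, spec, n_starts = 5, seed = 2)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("information criteria identities hold on a fit", {
  d <- sim_pref_data(34)
  f <- fit_model(d, model_spec("ALL_OR_NONE", unique(d$dose)),
                 n_starts = 5, seed = 3)
  expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
  expect_equal(f$bic, f$k * log(f$n_obs) - 2 * f$loglik)
  expect_equal(f$n_obs, nrow(d))
})

test_that("a free two-component mixture dominates its single-Gaussian component", {
  d <- sim_pref_data(35, doses = 2, per_dose = 60)
  qz <- fit_model(d, model_spec("QUANTIZED", 2), n_starts = 10, seed = 4)
  st <- qz$theta$sigma_tilde
  single <- sum(dnorm(d$p, qz$theta$mu_u,
                      sqrt(pmax(st^2 * qz$theta$mu_u *
                                  (1 - qz$theta$mu_u) / d$n, 1e-6)),
                      log = TRUE))
  expect_gte(qz$loglik, single - 1e-6)
})

test_that("all-or-none parameters are recovered from simulated truth", {
  cfg <- generative_config(cycle_doses = data.frame(
    n_cycles = c(0, 1, 2, 3, 4, 5, 10, 20),
    n_larvae = 80), seed = 55)
  d <- preference_data(simulate_experiment(cfg)$groups)
  f <- fit_model(d, model_spec("ALL_OR_NONE", study_doses),
                 n_starts = 5, seed = 6)
  expect_lt(abs(f$theta$lambda - 0.6), 0.08)
  expect_lt(abs(f$theta$mu_u - 0.27), 0.03)
  expect_lt(abs(f$theta$mu_t - 0.52), 0.03)
})

test_that("freed sigma-tilde is near 1 for independent Bernoulli choices", {
  cfg <- generative_config(serial_delta = 0,
                           cycle_doses = data.frame(n_cycles = c(0, 20),
                                                    n_larvae = 2000),
                           seed = 77)
  d <- preference_data(simulate_experiment(cfg)$groups)
  f <- fit_model(d, model_spec("ALL_OR_NONE", c(0, 20)), n_starts = 5,
                 seed = 7)
  expect_lt(abs(f$theta$sigma_tilde - 1), 0.1)
})

test_that("model comparison tabulates deltas and tolerates failures", {
  d <- sim_pref_data(36)
  cmp <- compare_models(d, models = c("ALL_OR_NONE", "ALL_OR_NONE"),
                        n_starts = 3, seed = 5)
  expect_equal(cmp$delta_logP, c(0, 0))
  expect_equal(cmp$delta_bic, c(0, 0))

  cmp2 <- compare_models(d, n_starts = 3, seed = 5)
  expect_equal(nrow(cmp2), 5)
  expect_true(all(cmp2$error == ""))
  expect_true(any(cmp2$delta_bic == 0))
  # rankings are invariant to adding a constant to all log-likelihoods
  expect_equal(order(cmp2$bic), order(cmp2$bic - 2 * min(cmp2$loglik)))
})

test_that("single-dose designs degrade gracefully", {
  d <- sim_pref_data(37, doses = 0, per_dose = 40)
  cmp <- compare_models(d, models = c("ALL_OR_NONE", "QUANTIZED"),
                        n_starts = 5, seed = 6)
  expect_true(all(cmp$error == ""))
  expect_gte(cmp$loglik[cmp$model == "QUANTIZED"],
             cmp$loglik[cmp$model == "ALL_OR_NONE"] - 1e-4)
})

test_that("memoryless untrained-fraction curve follows lambda powers", {
  d <- sim_pref_data(38)
  fits <- attr(compare_models(d, models = c("ALL_OR_NONE", "QUANTIZED"),
                              n_starts = 5, seed = 8), "fits")
  curve <- untrained_fraction_curve(fits$QUANTIZED, d,
                                    all_or_none_fit = fits$ALL_OR_NONE)
  lam <- fits$ALL_OR_NONE$theta$lambda
  expect_equal(curve$f_untrained_memoryless, lam^curve$dose)
  expect_equal(curve$f_untrained_memoryless[curve$dose == 0], 1)
  expect_true(all(curve$lower <= curve$f_untrained + 1e-8 &
                    curve$f_untrained <= curve$upper + 1e-8))
})
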