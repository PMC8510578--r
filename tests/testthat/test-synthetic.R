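test_that("memoryless untrained fraction follows the exponential decay", {
  expect_equal(analytic_untrained_fraction(0, 7), 1)
  expect_equal(analytic_untrained_fraction(1, 1), 0)
  expect_equal(analytic_untrained_fraction(0.3, 2), 0.49)
  expect_error(analytic_untrained_fraction(1.2, 1),
               class = "larvalearn_domain_error")
  i <- 0:20
  expect_true(all(diff(analytic_untrained_fraction(0.25, i)) <= 0))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(generative_config(mu_u = 1.2),
               class = "larvalearn_domain_error")
  expect_error(generative_config(serial_delta = 0.3),
               "serial_delta too large", class = "larvalearn_domain_error")
  expect_error(generative_config(cycle_doses = data.frame(n_cycles = integer(),
                                                          n_larvae = integer())),
               class = "larvalearn_domain_error")
})

test_that("zero serial correlation gives i.i.d. Bernoulli phases", {
  cfg <- generative_config(mu_t = 0.27, serial_delta = 0,
                           decisions_per_phase = list(mean = 500,
                                                      dispersion = 1e6,
                                                      min = 500),
                           seed = 5)
  sim <- simulate_larva(cfg, dose = 0, seed = 42)
  x <- as.integer(sim$record$decisions$PRE$outcome == "approach")
  # mean within binomial error, lag-1 correlation near zero
  expect_lt(abs(mean(x) - 0.27), 3 * sqrt(0.27 * 0.73 / length(x)))
  expect_lt(abs(cor(x[-1], x[-length(x)])), 3 / sqrt(length(x)))
})

test_that("certain training flips every animal after one cycle", {
  cfg <- generative_config(rho = 1,
                           cycle_doses = data.frame(n_cycles = c(1, 5),
                                                    n_larvae = c(10, 10)),
                           seed = 3)
  truth <- simulate_experiment(cfg)$truth
  expect_true(all(truth$final_state == "TRAINED"))
})

test_that("serially correlated stream has the target mean and negative lag-1", {
  mu <- 0.27; delta <- 0.08
  cfg <- generative_config(serial_delta = delta,
                           decisions_per_phase = list(mean = 1e5,
                                                      dispersion = 1e6,
                                                      min = 1e5),
                           seed = 1)
  x <- with(simulate_larva(cfg, 0, seed = 99)$record$decisions$PRE,
            as.integer(outcome == "approach"))
  n <- length(x)
  se <- sqrt(mu * (1 - mu) / n) * implied_sigma_tilde(mu, delta)
  expect_lt(abs(mean(x) - mu), 3 * se)
  phi_hat <- cor(x[-1], x[-n])
  phi <- -delta / (1 - mu)
  expect_lt(phi_hat, 0)
  expect_lt(abs(phi_hat - phi), 4 / sqrt(n))
})

test_that("simulated experiments are deterministic given the master seed", {
  cfg <- generative_config(cycle_doses = data.frame(n_cycles = c(0, 2),
                                                    n_larvae = c(5, 5)),
                           seed = 17)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_decision_table(a$groups, p1); write_decision_table(b$groups, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("per-animal streams are unperturbed by other dose groups", {
  small <- generative_config(cycle_doses = data.frame(n_cycles = 2,
                                                      n_larvae = 5),
                             seed = 17)
  big <- generative_config(cycle_doses = data.frame(n_cycles = c(0, 2),
                                                    n_larvae = c(50, 5)),
                           seed = 17)
  gs <- simulate_experiment(small)$groups[[1]]
  gb <- Filter(function(g) g$name == "dose_2",
               simulate_experiment(big)$groups)[[1]]
  expect_identical(gs$larvae$dose_2_L001$decisions,
                   gb$larvae$dose_2_L001$decisions)
})

test_that("dose-0 population preference approaches the untrained mean", {
  cfg <- generative_config(cycle_doses = data.frame(n_cycles = 0,
                                                    n_larvae = 300),
                           seed = 8)
  g <- simulate_experiment(cfg)$groups[[1]]
  pref <- population_preference(g, "PRE")
  expect_lt(abs(pref$value - 0.27), 3 * sqrt(0.27 * 0.73 / pref$n_decisions))
})

test_that("extinction reversion is all-or-none with the configured rate", {
  cfg <- generative_config(seed = 1)
  trained <- list(mode = "all_or_none", states = c("UNTRAINED", "TRAINED"),
                  final_state = "TRAINED", final_mean = cfg$mu_t)

  cfg0 <- generative_config(extinction_revert_prob = 0)
  t0 <- simulate_extinction_block(trained, 18, cfg0, seed = 4)
  expect_equal(t0$final_state, "TRAINED")

  cfg1 <- generative_config(extinction_revert_prob = 1)
  t1 <- simulate_extinction_block(trained, 1, cfg1, seed = 4)
  expect_equal(t1$final_state, "UNTRAINED")
  expect_equal(t1$final_mean, cfg1$mu_u)

  # survival after 18 cycles matches the closed form (1 - q)^18
  cfgq <- generative_config(extinction_revert_prob = 0.15)
  n <- 4000
  surv <- mean(vapply(seq_len(n), function(i)
    simulate_extinction_block(trained, 18, cfgq, seed = i)$final_state ==
      "TRAINED", logical(1)))
  expected <- 0.85^18
  expect_lt(abs(surv - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("all-or-none data are a two-component mixture in latent truth", {
  cfg <- generative_config(cycle_doses = data.frame(n_cycles = 2,
                                                    n_larvae = 400),
                           seed = 12)
  truth <- simulate_experiment(cfg)$truth
  expect_setequal(unique(truth$final_mean), c(cfg$mu_u, cfg$mu_t))
  cfg_g <- generative_config(mode = "graded",
                             cycle_doses = data.frame(n_cycles = 2,
                                                      n_larvae = 50),
                             seed = 12)
  truth_g <- simulate_experiment(cfg_g)$truth
  expect_equal(unique(truth_g$final_mean), 0.27 + 2 * cfg_g$graded_step)
})

test_that("per-animal preference variance matches the deflated variance model", {
  mu <- 0.27; delta <- 0.08; n_dec <- 40
  cfg <- generative_config(serial_delta = delta,
                           decisions_per_phase = list(mean = n_dec,
                                                      dispersion = 1e6,
                                                      min = n_dec),
                           cycle_doses = data.frame(n_cycles = 0,
                                                    n_larvae = 3000),
                           seed = 31)
  d <- preference_data(simulate_experiment(cfg)$groups, "PRE")
  st <- implied_sigma_tilde(mu, delta)
  expected <- variance_model(mu, n_dec, st)
  expect_lt(abs(var(d$p) / expected - 1), 0.12)
  expect_lt(var(d$p), mu * (1 - mu) / n_dec)  # deflation: sigma-tilde < 1
})
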