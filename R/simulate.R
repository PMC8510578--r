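#' Configuration of the generative choice simulator
#'
#' Describes the statistical structure the downstream analysis assumes:
#' animals grouped by training dose, per-animal decision counts of order
#' 10--40 per hour-long phase, serially anti-correlated binary choices,
#' an untrained mean preference near 0.27 and a trained mean near 0.52,
#' and per-cycle all-or-none switching (or, alternatively, graded drift).
#'
#' Serial correlation is a two-state Markov chain on the previous choice:
#' after an approach the next approach probability is `m - delta`, after
#' an avoid it is `m + m*delta/(1-m)`, which makes the stationary mean
#' exactly `m` while giving lag-1 autocorrelation `-delta/(1-m)` (the
#' animal is less likely to choose the CO2 channel right after choosing
#' it).  The first choice of a phase is drawn at the marginal mean.
#'
#' @param mu_u untrained mean preference.
#' @param mu_t trained mean preference.
#' @param rho per-training-cycle probability that an untrained animal
#'   switches to the trained state (all-or-none mode); the expected
#'   untrained fraction after i cycles is `(1-rho)^i`.
#' @param serial_delta magnitude of the post-approach probability
#'   decrement (0 gives i.i.d. choices).
#' @param decisions_per_phase list with `mean`, `dispersion` (negative
#'   binomial size), and `min` for the per-phase decision-count draw.
#' @param cycle_doses data.frame with columns `n_cycles` and `n_larvae`:
#'   the dose design.  Defaults to the study design (doses 0--20, group
#'   sizes as published).
#' @param extinction_revert_prob per-unrewarded-cycle probability that a
#'   trained animal reverts to the untrained state.
#' @param mode `"all_or_none"` (latent two-state switching) or `"graded"`
#'   (latent mean drifts by `graded_step` per cycle, clipped to \[0,1\]).
#' @param graded_step per-cycle latent-mean increment in graded mode.
#'   The default reaches `mu_t` exactly at 20 cycles.
#' @param seed master seed; per-animal streams are derived by counter
#'   mixing so that changing one dose group does not perturb the others.
#' @return A validated list of class `generative_config`.
#' @export
generative_config <- function(mu_u = 0.27, mu_t = 0.52, rho = 0.4,
                              serial_delta = 0.08,
                              decisions_per_phase = list(mean = 30,
                                                         dispersion = 8,
                                                         min = 1),
                              cycle_doses = data.frame(
                                n_cycles = c(0, 1, 2, 3, 4, 5, 10, 20),
                                n_larvae = c(50, 35, 87, 31, 32, 63, 14, 64)),
                              extinction_revert_prob = 0.15,
                              mode = c("all_or_none", "graded"),
                              graded_step = (0.52 - 0.27) / 20,
                              seed = 1L) {
  mode <- match.arg(mode)
  for (p in list(mu_u = mu_u, mu_t = mu_t, rho = rho,
                 extinction_revert_prob = extinction_revert_prob))
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
      domain_error("probabilities must be single values in [0, 1]")
  if (serial_delta < 0) domain_error("serial_delta must be >= 0")
  for (m in c(mu_u, mu_t)) {
    if (m - serial_delta < 0 || m + m * serial_delta / max(1 - m, 1e-12) > 1)
      domain_error(
        "serial_delta too large for mean %.3f: transition probabilities leave [0, 1]", m)
  }
  dp <- decisions_per_phase
  if (!all(c("mean", "dispersion", "min") %in% names(dp)) || dp$min < 0)
    domain_error("decisions_per_phase needs mean, dispersion, min (min >= 0)")
  stopifnot(is.data.frame(cycle_doses),
            all(c("n_cycles", "n_larvae") %in% names(cycle_doses)))
  if (nrow(cycle_doses) == 0) domain_error("cycle_doses must be non-empty")
  structure(list(mu_u = mu_u, mu_t = mu_t, rho = rho,
                 serial_delta = serial_delta, decisions_per_phase = dp,
                 cycle_doses = cycle_doses,
                 extinction_revert_prob = extinction_revert_prob,
                 mode = mode, graded_step = graded_step,
                 seed = as.integer(seed)),
            class = "generative_config")
}

#' Read a generative configuration from a YAML file
#'
#' Keys mirror the arguments of [generative_config]; absent keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return A `generative_config`.
#' @export
read_generative_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cycle_doses)) raw$cycle_doses <-
      as.data.frame(lapply(as.data.frame(raw$cycle_doses), unlist))
  do.call(generative_config, raw)
}

#' Expected untrained fraction under memoryless all-or-none learning
#'
#' If every training cycle converts each still-untrained animal with the
#' same probability `rho`, regardless of its history, the untrained
#' fraction decays exponentially: `(1 - rho)^i` after `i` cycles.
#'
#' @param rho per-cycle training probability, in \[0, 1\].
#' @param i number of training cycles (vectorized, `i >= 0`).
#' @return `(1 - rho)^i`.
#' @export
analytic_untrained_fraction <- function(rho, i) {
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) || rho < 0 || rho > 1)
    domain_error("rho must be a single probability in [0, 1]")
  if (any(i < 0)) domain_error("i must be >= 0")
  (1 - rho)^i
}

#' Variance deflation implied by the serial correlation
#'
#' For the simulator's two-state choice chain at stationary mean `mu` with
#' post-approach decrement `delta`, the lag-1 autocorrelation is
#' `phi = -delta/(1-mu)` and the large-n variance of the per-animal mean is
#' `(1+phi)/(1-phi)` times the binomial value -- i.e. the sigma-tilde of
#' the variance model.  Anti-correlated choices give sigma-tilde < 1.
#'
#' @param mu stationary mean preference.
#' @param delta post-approach probability decrement.
#' @return Implied sigma-tilde (scalar multiplier on the binomial sd).
#' @export
implied_sigma_tilde <- function(mu, delta) {
  phi <- -delta / (1 - mu)
  sqrt((1 + phi) / (1 - phi))
}

# draw n serially correlated binary choices at stationary mean m
# (1 = approach); assumes the RNG is already seeded by the caller
markov_choices <- function(n, m, delta) {
  if (n <= 0) return(integer())
  if (m <= 0) return(rep(0L, n))
  if (m >= 1) return(rep(1L, n))
  p_after_app <- m - delta
  p_after_avoid <- m + m * delta / (1 - m)
  u <- runif(n)
  x <- integer(n)
  x[1] <- as.integer(u[1] < m)
  if (n > 1) for (i in 2:n)
    x[i] <- as.integer(u[i] < if (x[i - 1] == 1L) p_after_app else p_after_avoid)
  x
}

draw_n_decisions <- function(config) {
  dp <- config$decisions_per_phase
  max(dp$min, rnbinom(1, mu = dp$mean, size = dp$dispersion))
}

#' Simulate one animal
#'
#' Draws the PRE phase at the untrained mean, runs the latent training
#' trajectory for `dose` cycles (all-or-none Bernoulli switching or graded
#' drift, per the configuration), then draws the POST phase at the final
#' latent mean.  All draws come from a stream derived from `seed`, so a
#' record is reproducible independently of any other animal.
#'
#' @param config a [generative_config].
#' @param dose number of training cycles for this animal.
#' @param seed per-animal stream seed.
#' @param larva_id,group identity fields for the returned record.
#' @return List with `record` (a [larva_record]) and `truth` (the latent
#'   trajectory: per-cycle `states` or `means`, plus `final_state` and
#'   `final_mean`).
#' @export
simulate_larva <- function(config, dose, seed, larva_id = "sim1",
                           group = "sim") {
  stopifnot(inherits(config, "generative_config"))
  dose <- as.integer(dose)
  with_seed(seed, {
    n_pre <- draw_n_decisions(config)
    pre <- markov_choices(n_pre, config$mu_u, config$serial_delta)
    if (config$mode == "all_or_none") {
      states <- character(dose + 1L)
      states[1] <- "UNTRAINED"
      for (i in seq_len(dose))
        states[i + 1L] <- if (states[i] == "TRAINED") "TRAINED"
          else if (runif(1) < config$rho) "TRAINED" else "UNTRAINED"
      final_state <- states[dose + 1L]
      final_mean <- if (final_state == "TRAINED") config$mu_t else config$mu_u
      truth <- list(mode = "all_or_none", states = states,
                    final_state = final_state, final_mean = final_mean)
    } else {
      means <- pmin(1, pmax(0, config$mu_u + (0:dose) * config$graded_step))
      final_mean <- means[dose + 1L]
      truth <- list(mode = "graded", means = means,
                    final_state = NA_character_, final_mean = final_mean)
    }
    n_post <- draw_n_decisions(config)
    post <- markov_choices(n_post, final_mean, config$serial_delta)
    dec <- list()
    if (n_pre > 0) dec$PRE <- decision_frame(OUTCOMES[2L - pre])
    if (n_post > 0) dec$POST <- decision_frame(OUTCOMES[2L - post])
    list(record = larva_record(larva_id, group, dose, dec), truth = truth)
  })
}

#' Simulate a full dose-response experiment
#'
#' One group per training dose in `config$cycle_doses`, with the
#' configured group sizes.  Deterministic given `config$seed`; the latent
#' truth is returned alongside the records so that recovery experiments
#' can compare estimates against it.
#'
#' @param config a [generative_config].
#' @return List with `groups` (list of [experiment_group], one per dose,
#'   named `dose_<n>`) and `truth` (data.frame: `larva_id`, `group`,
#'   `n_cycles`, `final_state`, `final_mean`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  groups <- list(); truth <- list()
  for (d in seq_len(nrow(config$cycle_doses))) {
    dose <- config$cycle_doses$n_cycles[d]
    size <- config$cycle_doses$n_larvae[d]
    gname <- sprintf("dose_%d", dose)
    larvae <- vector("list", size)
    for (j in seq_len(size)) {
      sim <- simulate_larva(config, dose,
                            seed = mix_seed(config$seed, dose, j),
                            larva_id = sprintf("%s_L%03d", gname, j),
                            group = gname)
      larvae[[j]] <- sim$record
      truth[[length(truth) + 1L]] <- data.frame(
        larva_id = sim$record$larva_id, group = gname, n_cycles = dose,
        final_state = sim$truth$final_state,
        final_mean = sim$truth$final_mean)
    }
    groups[[gname]] <- experiment_group(gname, larvae,
                                        protocol = list(n_cycles = dose))
  }
  list(groups = unname(groups),
       truth = if (length(truth))
         do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Apply an unrewarded extinction block to a latent trajectory
#'
#' Each unrewarded CO2 presentation reverts a trained animal to the
#' untrained state with probability `config$extinction_revert_prob`;
#' untrained animals are unaffected.  Reversion is all-or-none: an
#' extinguished animal returns to the untrained mean, never to an
#' intermediate state.  Only the latent truth changes; post-extinction
#' decisions should be drawn after applying this (see
#' [simulate_phase_decisions]).
#'
#' @param truth a `truth` list from [simulate_larva] (all-or-none mode).
#' @param n_unrewarded number of unrewarded cycles (the study used 18).
#' @param config a [generative_config].
#' @param seed stream seed for the reversion draws.
#' @return The updated truth list, with an `extinction_states` trajectory
#'   appended.
#' @export
simulate_extinction_block <- function(truth, n_unrewarded = 18, config,
                                      seed = 1L) {
  if (!identical(truth$mode, "all_or_none"))
    domain_error("extinction is defined for all_or_none truth")
  state <- truth$final_state
  states <- character(n_unrewarded)
  with_seed(seed, {
    for (i in seq_len(n_unrewarded)) {
      if (state == "TRAINED" && runif(1) < config$extinction_revert_prob)
        state <- "UNTRAINED"
      states[i] <- state
    }
  })
  truth$extinction_states <- states
  truth$final_state <- state
  truth$final_mean <- if (state == "TRAINED") config$mu_t else config$mu_u
  truth
}

#' Draw one phase of decisions at a given latent state
#'
#' @param truth a truth list (its `final_mean` sets the chain mean).
#' @param config a [generative_config].
#' @param seed stream seed.
#' @param n optional decision count; drawn from the configured count law
#'   when `NULL`.
#' @return A [decision_frame].
#' @export
simulate_phase_decisions <- function(truth, config, seed, n = NULL) {
  with_seed(seed, {
    if (is.null(n)) n <- draw_n_decisions(config)
    x <- markov_choices(n, truth$final_mean, config$serial_delta)
    decision_frame(if (n > 0) OUTCOMES[2L - x] else character())
  })
}
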