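# shared fixtures and independent oracles

# quick record builder: outcomes as strings of a/v, e.g. pre = "aav"
make_record <- function(id, pre = "", post = "", n_cycles = 0, group = "g",
                        next_day = "") {
  tok <- function(s) {
    if (!nzchar(s)) return(NULL)
    ch <- strsplit(s, "")[[1]]
    decision_frame(ifelse(ch == "a", "approach", "avoid"))
  }
  dec <- Filter(Negate(is.null),
                list(PRE = tok(pre), POST = tok(post), NEXT_DAY = tok(next_day)))
  larva_record(id, group, n_cycles, dec)
}

make_group <- function(..., name = "g") {
  experiment_group(name, list(...))
}

# independent Fisher oracle: full hypergeometric enumeration over all
# tables with the observed margins; two-sided by the point-probability rule
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# dense grid scan of the trained-fraction profile log-likelihood:
# the independent oracle for the half-unit-drop interval endpoints
grid_profile_interval <- function(data, theta0, step = 1e-4) {
  fgrid <- seq(0, 1, by = step)
  ldu <- dnorm(data$p, theta0$mu_u,
               sqrt(pmax(theta0$sigma_tilde^2 * theta0$mu_u *
                           (1 - theta0$mu_u) / data$n, 1e-6)), log = TRUE)
  ldt <- dnorm(data$p, theta0$mu_t,
               sqrt(pmax(theta0$sigma_tilde^2 * theta0$mu_t *
                           (1 - theta0$mu_t) / data$n, 1e-6)), log = TRUE)
  ll <- vapply(fgrid, function(f) {
    s1 <- log1p(-f) + ldu; s2 <- log(f) + ldt
    m <- pmax(s1, s2)
    sum(m + log(exp(s1 - m) + exp(s2 - m)))
  }, numeric(1))
  keep <- fgrid[ll >= max(ll) - 0.5]
  c(f0 = fgrid[which.max(ll)], lower = min(keep), upper = max(keep))
}

# small simulated dataset for model tests
sim_pref_data <- function(seed, doses = c(0, 2, 20), per_dose = 25,
                          mode = "all_or_none", ...) {
  cfg <- generative_config(cycle_doses = data.frame(n_cycles = doses,
                                                    n_larvae = per_dose),
                           mode = mode, seed = seed, ...)
  preference_data(simulate_experiment(cfg)$groups)
}
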