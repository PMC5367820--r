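# Shared fixtures: registry-scale parameter sets for each model (magnitudes
# typical of pooled age-specific incidence fits of an adult solid cancer),
# the default population schedule, and noise-free table construction.

registry_pars <- list(
  m2 = c(p = -0.129, q = 6.21e-6, r = 1.50e-2),
  m3 = c(p = -0.138, q = 1.57e-5, r = 2.35e-2),
  m4 = c(p = -0.150, q = 4.59e-5, r = 2.66e-2)
)

pq_of <- function(pars) structure(list(p = pars[["p"]], q = pars[["q"]]),
                                  class = "pq_pair")

default_schedule <- function() population_schedule()

# table whose counts are the rounded expected counts (zero-noise data)
noise_free_table <- function(model, pars, schedule = default_schedule()) {
  shell <- incidence_table(schedule$age_lo, schedule$age_hi,
                           rep(0L, nrow(schedule)), schedule$person_years)
  E <- expected_cases(model, pars, shell)
  incidence_table(schedule$age_lo, schedule$age_hi, round(E),
                  schedule$person_years)
}

# random valid branching-process rate draws for property loops
random_abm <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(alpha = exp(stats::runif(n, log(0.1), log(20))),
             beta = exp(stats::runif(n, log(0.01), log(10))),
             mu = exp(stats::runif(n, log(1e-8), log(0.5))))
}
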