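# Shared fixtures, all built in code.

# Two subjects, one 500-mg infusion each, two observations each.
tiny_events <- function() {
  data.frame(
    ID = rep(1:2, each = 3),
    TIME = rep(c(0, 1, 6), 2),
    AMT = rep(c(500, NA, NA), 2),
    DUR = rep(c(0.5, NA, NA), 2),
    DV = rep(c(NA, 60, 2.5), 2),
    EVID = rep(c(1, 0, 0), 2),
    MDV = rep(c(1, 0, 0), 2),
    WT = rep(c(10, 11), each = 3),
    AGE = rep(c(1.0, 1.5), each = 3),
    SEX = rep(c(0, 1), each = 3),
    SCR = rep(c(18, 20), each = 3),
    HT = rep(c(75, 80), each = 3))
}

tiny_dataset <- function() pk_dataset(tiny_events())

# Study-scale synthetic trial (20 infants, sparse sampling).
study_dataset <- function(seed = 7, model = arc_infant_model()) {
  pop <- generate_population(20, seed = seed)
  simulate_trial(pop, model, seed = seed + 1000)
}

# Rich design: every subject contributes 6 samples.
rich_design <- function() {
  sampling_design(n_samples_probs = c(0, 0, 0, 0, 0, 1),
                  windows = list(c(0.5, 2), c(2, 8), c(8, 12)),
                  window_weights = c(0.3, 0.4, 0.3))
}

# Truncated-normal CDF and mean (closed form) for distributional checks.
ptrunc_norm <- function(x, m, s, lo, hi) {
  (pnorm(x, m, s) - pnorm(lo, m, s)) / (pnorm(hi, m, s) - pnorm(lo, m, s))
}
trunc_norm_mean <- function(m, s, lo, hi) {
  a <- (lo - m) / s; b <- (hi - m) / s
  m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Naive -2 log likelihood at eta = 0 (exponential error), computed without
# the FOCE kernel: the Omega -> 0 reference.
naive_m2ll <- function(ds, model) {
  tv <- typical_params(model, ds$subjects$weight, ds$subjects$age,
                       egfr = ds$subjects$egfr, sex = ds$subjects$sex)
  total <- 0
  ev <- ds$events
  for (i in seq_len(nrow(ds$subjects))) {
    id <- ds$subjects$id[i]
    d <- ev[ev$id == id, ]
    obs <- d[d$evid == 0 & d$mdv == 0 & !d$below_lloq, ]
    dose <- d[d$evid == 1, ]
    if (nrow(obs) == 0) next
    pred <- concentration(obs$time,
                          data.frame(time = dose$time, amount = dose$amt,
                                     duration = dose$dur),
                          list(cl = tv$cl[i], v = tv$v[i]))
    total <- total - 2 * sum(dnorm(log(obs$dv), log(pred),
                                   sqrt(model$sigma2), log = TRUE))
  }
  total
}
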