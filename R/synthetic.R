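#' Virtual ARC-infant population specification
#'
#' Covariate distributions of the study cohort: weight and age are
#' truncated normals matching the reported mean (SD) and range, serum
#' creatinine likewise, sex is balanced, and height (needed only for the
#' Schwartz eGFR / ARC filter) follows a piecewise-linear length-for-age
#' curve with Gaussian noise. Weight and age share a latent factor giving
#' them a positive correlation, as in real infant cohorts; set
#' `wt_age_cor = 0` for uncorrelated draws in recovery experiments.
#'
#' @param weight_mean,weight_sd,weight_range weight distribution, kg.
#' @param age_mean,age_sd,age_range age distribution, years.
#' @param scr_mean,scr_sd,scr_range serum creatinine, umol/L.
#' @param wt_age_cor latent weight-age correlation in `[0, 1)`.
#' @param height_sd noise SD around the length-for-age curve, cm.
#' @param arc_min minimum eGFR (mL/min/1.73 m^2) enforced by redrawing
#'   creatinine and height; set to `0` to disable the ARC filter.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(weight_mean = 10.33, weight_sd = 1.57,
                            weight_range = c(8.00, 13.00),
                            age_mean = 1.20, age_sd = 0.43,
                            age_range = c(0.35, 1.86),
                            scr_mean = 18, scr_sd = 6,
                            scr_range = c(10, 26),
                            wt_age_cor = 0.6, height_sd = 2,
                            arc_min = 130) {
  chk <- function(m, s, r, what) {
    if (r[1] >= r[2]) stop(what, ": invalid range")
    if (r[2] < m - 4 * s || r[1] > m + 4 * s)
      stop("infeasible spec: ", what, " bounds exclude mean +/- 4 SD")
  }
  chk(weight_mean, weight_sd, weight_range, "weight")
  chk(age_mean, age_sd, age_range, "age")
  chk(scr_mean, scr_sd, scr_range, "scr")
  if (wt_age_cor < 0 || wt_age_cor >= 1) stop("wt_age_cor must be in [0, 1)")
  structure(list(weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_range = weight_range, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 scr_mean = scr_mean, scr_sd = scr_sd,
                 scr_range = scr_range, wt_age_cor = wt_age_cor,
                 height_sd = height_sd, arc_min = arc_min),
            class = "population_spec")
}

# Infant length-for-age (cm): piecewise linear through standard growth
# magnitudes (~66 cm at 0.35 y, 75 cm at 1 y, 87 cm at 2 y).
length_for_age <- function(age) {
  stats::approx(x = c(0.35, 1, 2), y = c(66, 75, 87), xout = age,
                rule = 2)$y
}

#' Generate a virtual infant population
#'
#' Draws covariate vectors from the truncated normals of a
#' [population_spec()]. Weight and age are coupled through a shared latent
#' Gaussian factor and mapped to their truncated-normal marginals by the
#' quantile transform (a Gaussian copula), so the marginal distributions
#' match the cohort summaries exactly while weight and age remain
#' positively correlated. Serum creatinine and height are then redrawn per
#' subject until the Schwartz eGFR meets the ARC criterion, preserving the
#' requested `n`.
#'
#' @param n number of virtual subjects (>= 1).
#' @param spec a [population_spec()].
#' @param seed integer RNG seed.
#' @return data.frame of class `virtual_population`: `id`, `weight`, `age`,
#'   `sex` (0 = male, 1 = female, balanced), `scr`, `height`, `egfr`,
#'   `arc`.
#' @export
generate_population <- function(n, spec = population_spec(), seed = 1) {
  stopifnot(n >= 1, inherits(spec, "population_spec"))
  set.seed(seed)
  qtrunc <- function(u, m, s, r) {
    plo <- pnorm(r[1], m, s); phi <- pnorm(r[2], m, s)
    qnorm(plo + u * (phi - plo), m, s)
  }
  lam <- sqrt(spec$wt_age_cor)             # equal loadings: latent cor = lam^2
  res <- sqrt(1 - spec$wt_age_cor)
  z <- rnorm(n); e1 <- rnorm(n); e2 <- rnorm(n)
  weight <- qtrunc(pnorm(lam * z + res * e1), spec$weight_mean,
                   spec$weight_sd, spec$weight_range)
  age <- qtrunc(pnorm(lam * z + res * e2), spec$age_mean, spec$age_sd,
                spec$age_range)
  scr <- height <- egfr <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      s <- rnorm(1, spec$scr_mean, spec$scr_sd)
      if (s < spec$scr_range[1] || s > spec$scr_range[2]) next
      h <- length_for_age(age[i]) + rnorm(1, 0, spec$height_sd)
      if (h <= 0) next
      g <- compute_egfr(s, h)
      if (g >= spec$arc_min) {
        scr[i] <- s; height[i] <- h; egfr[i] <- g
        break
      }
    }
  }
  sex <- rep_len(c(0, 1), n)[sample.int(n)]
  out <- data.frame(id = seq_len(n), weight = weight, age = age, sex = sex,
                    scr = scr, height = height, egfr = egfr,
                    arc = egfr >= 130)
  class(out) <- c("virtual_population", "data.frame")
  out
}

#' Sparse opportunistic sampling design
#'
#' Scavenged-sampling emulation: each subject contributes 1-3 samples
#' (default probabilities 0.4/0.4/0.2, mean 1.8, so 20 subjects yield about
#' 36 samples), at times drawn uniformly within post-dose windows spanning
#' the end of the infusion through the trough.
#'
#' @param n_samples_probs probabilities that a subject contributes 1, 2,
#'   ..., `length(n_samples_probs)` samples; the default (0.4, 0.4, 0.2)
#'   gives 1-3 samples with mean 1.8.
#' @param windows list of `c(lo, hi)` windows, h after a dose.
#' @param window_weights sampling weight per window.
#' @param n_doses number of administered doses per subject before/during
#'   sampling.
#' @param fixed_times optional deterministic rich design: every subject is
#'   sampled at exactly these times (h after the start of the last dose),
#'   and the window machinery is ignored.
#' @return an object of class `sampling_design`.
#' @export
sampling_design <- function(n_samples_probs = c(0.4, 0.4, 0.2),
                            windows = list(c(0.5, 2), c(2, 8), c(8, 12)),
                            window_weights = c(0.3, 0.4, 0.3),
                            n_doses = 4, fixed_times = NULL) {
  stopifnot(length(n_samples_probs) >= 1,
            abs(sum(n_samples_probs) - 1) < 1e-8,
            length(windows) == length(window_weights))
  if (!is.null(fixed_times))
    stopifnot(all(fixed_times > 0), !is.unsorted(fixed_times))
  structure(list(n_samples_probs = n_samples_probs, windows = windows,
                 window_weights = window_weights / sum(window_weights),
                 n_doses = n_doses, fixed_times = fixed_times),
            class = "sampling_design")
}

#' Simulate a sparse-sampling PK trial
#'
#' Generates a synthetic trial dataset with the statistical structure the
#' estimation pipeline assumes: each virtual subject receives the regimen
#' on their own weight, individual parameters are drawn from the model's
#' lognormal IIV, observation times follow the sampling design relative to
#' a random administered dose, and concentrations carry residual error
#' (multiplicative lognormal for the exponential error model). Samples that
#' land below the assay LLOQ are redrawn at a different time, reflecting a
#' cohort in which all quantified samples were above the LLOQ.
#'
#' @param population a `virtual_population` from [generate_population()].
#' @param model a [pop_model()].
#' @param design a [sampling_design()].
#' @param reg a [regimen()] (default 100 mg/kg/day q12h, 0.5-h infusions).
#' @param seed integer RNG seed.
#' @param lloq lower limit of quantification, mg/L.
#' @return a [pk_dataset()].
#' @export
simulate_trial <- function(population, model, design = sampling_design(),
                           reg = regimen(100, 12), seed = 1, lloq = 0.03) {
  stopifnot(inherits(model, "pop_model"), inherits(design, "sampling_design"))
  set.seed(seed)
  tv <- typical_params(model, population$weight, population$age,
                       egfr = population$egfr, sex = population$sex)
  rows <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    doses <- dose_events(reg, population$weight[i], design$n_doses)
    eta <- rnorm(2) * sqrt(c(model$omega2[["cl"]], model$omega2[["v"]]))
    ipar <- list(cl = tv$cl[i] * exp(eta[1]), v = tv$v[i] * exp(eta[2]))
    if (!is.null(design$fixed_times)) {
      times <- doses$time[design$n_doses] + design$fixed_times
      pred <- concentration(times, doses, ipar)
      conc <- switch(model$error,
        exponential = pred * exp(rnorm(length(pred), 0,
                                       sqrt(model$sigma2))),
        additive = pred + rnorm(length(pred), 0, sqrt(model$sigma2)),
        combined = pred + rnorm(length(pred)) *
          sqrt(model$sigma2[["add"]] + model$sigma2[["prop"]] * pred^2))
    } else {
      n_s <- sample(seq_along(design$n_samples_probs), 1,
                    prob = design$n_samples_probs)
      times <- conc <- numeric(n_s)
      for (j in seq_len(n_s)) {
        for (try in 1:50) {
          w <- design$windows[[sample(length(design$windows), 1,
                                      prob = design$window_weights)]]
          dose_idx <- sample(design$n_doses, 1)
          tt <- doses$time[dose_idx] + runif(1, w[1], w[2])
          pred <- concentration(tt, doses, ipar)
          y <- switch(model$error,
            exponential = pred * exp(rnorm(1, 0, sqrt(model$sigma2))),
            additive = pred + rnorm(1, 0, sqrt(model$sigma2)),
            combined = pred + rnorm(1, 0, sqrt(model$sigma2[["add"]] +
                                                 model$sigma2[["prop"]] * pred^2)))
          if (y >= lloq) break
        }
        times[j] <- tt; conc[j] <- y
      }
    }
    sub <- population[i, ]
    mk <- function(time, amt, dur, dv, evid, mdv)
      data.frame(ID = sub$id, TIME = time, AMT = amt, DUR = dur, DV = dv,
                 EVID = evid, MDV = mdv,
                 WT = sub$weight, AGE = sub$age, SEX = sub$sex,
                 SCR = sub$scr, HT = sub$height)
    dose_rows <- mk(doses$time, doses$amount, doses$duration, NA_real_, 1, 1)
    obs_rows <- mk(times, NA_real_, NA_real_, conc, 0, 0)
    rows[[i]] <- rbind(dose_rows, obs_rows)
  }
  pk_dataset(do.call(rbind, rows), lloq = lloq)
}
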