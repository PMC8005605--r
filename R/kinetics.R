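#' Dosing regimen
#'
#' An intermittent-infusion regimen expressed per kilogram: the total daily
#' dose is split evenly across `24/interval` infusions per day, so the
#' per-dose amount for a subject is `daily_dose * weight * interval / 24` mg.
#'
#' @param daily_dose total daily dose, mg/kg/day.
#' @param interval dosing interval, h; must divide 24.
#' @param duration infusion duration, h (default 0.5, i.e. 30 min).
#' @param label optional label; defaults to e.g. `"100 mg/kg/day q12h"`.
#' @return an object of class `regimen`.
#' @export
regimen <- function(daily_dose, interval, duration = 0.5, label = NULL) {
  if (daily_dose <= 0) stop("daily_dose must be positive")
  if (interval <= 0 || 24 %% interval != 0) stop("interval must divide 24 h")
  if (duration <= 0 || duration > interval) stop("invalid infusion duration")
  if (is.null(label))
    label <- sprintf("%g mg/kg/day q%gh", daily_dose, interval)
  structure(list(daily_dose = daily_dose, interval = interval,
                 duration = duration, label = label), class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("%s (%.2g-h infusions of %g mg/kg)\n", x$label, x$duration,
              x$daily_dose * x$interval / 24))
  invisible(x)
}

#' Per-dose amount for a subject
#' @param reg a [regimen()].
#' @param weight body weight, kg.
#' @return dose amount per administration, mg.
#' @export
dose_amount <- function(reg, weight) reg$daily_dose * weight * reg$interval / 24

#' Dose events implementing a regimen
#'
#' Expands a [regimen()] into explicit dose events for a subject, starting
#' at time 0.
#'
#' @param reg a [regimen()].
#' @param weight body weight, kg.
#' @param n_doses number of administrations.
#' @return data.frame with columns `time` (h), `amount` (mg), `duration` (h).
#' @export
dose_events <- function(reg, weight, n_doses) {
  data.frame(time = reg$interval * (seq_len(n_doses) - 1),
             amount = dose_amount(reg, weight),
             duration = reg$duration)
}

#' Concentration after arbitrary infusion doses
#'
#' Analytic one-compartment solution with zero-order (constant-rate)
#' infusion input and first-order elimination, superposed over a sequence of
#' dose events. Each dose with infusion rate `R0 = amount/duration`
#' contributes, at elapsed time `s` since its start,
#' \deqn{(R_0/CL)\,(1 - e^{-k_e \min(s, D)})\, e^{-k_e \max(0, s - D)}}
#' and nothing for `s < 0`.
#'
#' @param t times, h (vectorized).
#' @param doses data.frame with columns `time`, `amount`, `duration`
#'   (see [dose_events()]).
#' @param params one-row data.frame or list with `cl` (L/h) and `v` (L).
#' @return total drug concentration, mg/L, at each `t`.
#' @export
concentration <- function(t, doses, params) {
  cl <- params$cl[1]; v <- params$v[1]
  if (cl <= 0 || v <= 0) stop("cl and v must be positive")
  ke <- cl / v
  conc <- numeric(length(t))
  for (d in seq_len(nrow(doses))) {
    s <- t - doses$time[d]
    D <- doses$duration[d]
    r0 <- doses$amount[d] / D
    a <- pmin(s, D)
    b <- pmax(0, s - D)
    contrib <- (r0 / cl) * (1 - exp(-ke * a)) * exp(-ke * b)
    conc <- conc + ifelse(s > 0, contrib, 0)
  }
  conc
}

# Steady-state intermittent-infusion concentration at times t within one
# interval [0, tau), via the geometric-series superposition limit.
# Vectorized over subjects; t is recycled against (r0, cl, ke).
ss_conc <- function(t, r0, cl, ke, duration, tau) {
  cp <- r0 / cl
  q <- exp(-ke * tau)
  big_b <- expm1(ke * duration)           # e^{ke D} - 1
  k0 <- big_b * q / (1 - q)               # trough / Cp at t = 0
  during <- cp * (1 - exp(-ke * t) * (1 - k0))
  after <- cp * big_b * exp(-ke * t) / (1 - q)
  ifelse(t < duration, during, after)
}

#' Steady-state concentration profile over one dosing interval
#'
#' Analytic steady-state profile of an intermittent-infusion regimen
#' (geometric-series accumulation limit of the dose superposition), sampled
#' on a regular time grid across one interval. Time 0 is the start of an
#' infusion, so the profile rises to its peak at the end of the infusion and
#' decays mono-exponentially to the trough.
#'
#' @param reg a [regimen()].
#' @param weight body weight, kg.
#' @param params one-row data.frame or list with `cl` (L/h), `v` (L).
#' @param resolution grid spacing, h; must be <= 0.01.
#' @return data.frame with columns `time` (h in `[0, interval]`) and
#'   `conc` (mg/L).
#' @export
steady_state_interval <- function(reg, weight, params, resolution = 0.005) {
  if (resolution > 0.01) stop("resolution must be <= 0.01 h")
  cl <- params$cl[1]; v <- params$v[1]
  ke <- cl / v
  amt <- dose_amount(reg, weight)
  tt <- seq(0, reg$interval, by = resolution)
  data.frame(time = tt,
             conc = ss_conc(tt, amt / reg$duration, cl, ke,
                            reg$duration, reg$interval))
}

#' Steady-state daily exposure
#'
#' At steady state the 24-h area under the concentration-time curve equals
#' (daily dose)/CL, independent of the infusion schedule.
#'
#' @inheritParams steady_state_interval
#' @return AUC over 24 h at steady state, mg*h/L.
#' @export
ss_auc24 <- function(reg, weight, params) {
  reg$daily_dose * weight / params$cl[1]
}

#' Fraction of the dosing interval with free concentration above MIC
#'
#' Computes fT>MIC at steady state: the fraction of one dosing interval
#' during which the unbound concentration (`unbound_fraction` times the
#' total concentration) exceeds the MIC. The steady-state profile is
#' piecewise mono-exponential, so the up-crossing (during the infusion) and
#' down-crossing (during washout) times are solved in closed form.
#'
#' Vectorized over subjects: `weight` and the rows of `params` are recycled
#' to a common length.
#'
#' @param reg a [regimen()].
#' @param weight body weight, kg.
#' @param params data.frame with columns `cl`, `v` (one row per subject).
#' @param mic minimum inhibitory concentration, mg/L (scalar).
#' @param unbound_fraction unbound drug fraction in (0, 1]; default 0.77.
#' @return fraction in `[0, 1]` per subject.
#' @examples
#' ft_above_mic(regimen(100, 12), 10.25,
#'              typical_params(arc_infant_model(), 10.25, 1.25), mic = 0.25)
#' @export
ft_above_mic <- function(reg, weight, params, mic, unbound_fraction = 0.77) {
  if (mic <= 0) stop("mic must be positive")
  if (unbound_fraction <= 0 || unbound_fraction > 1)
    stop("unbound_fraction must be in (0, 1]")
  n <- max(length(weight), nrow(params))
  weight <- rep_len(weight, n)
  cl <- rep_len(params$cl, n); v <- rep_len(params$v, n)
  ke <- cl / v
  tau <- reg$interval; D <- reg$duration
  r0 <- dose_amount(reg, weight) / D
  cp <- r0 / cl
  q <- exp(-ke * tau)
  big_b <- expm1(ke * D)
  k0 <- big_b * q / (1 - q)               # trough fraction of Cp
  peak <- (1 - exp(-ke * D)) / (1 - q)    # peak fraction of Cp
  u <- mic / (unbound_fraction * cp)      # threshold as a fraction of Cp
  out <- numeric(n)
  out[u <= k0] <- 1                       # above MIC for the whole interval
  mid <- u < peak & u > k0                # one up- and one down-crossing
  if (any(mid)) {
    t_up <- -log((1 - u[mid]) / (1 - k0[mid])) / ke[mid]
    t_down <- log(big_b[mid] / (u[mid] * (1 - q[mid]))) / ke[mid]
    out[mid] <- pmin(1, pmax(0, (t_down - t_up) / tau))
  }
  out
}
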