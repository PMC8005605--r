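tp_ref <- function() typical_params(arc_infant_model(), 10.25, 1.25)

test_that("single-infusion concentration matches the closed form", {
  d <- data.frame(time = 0, amount = 500, duration = 0.5)
  p <- tp_ref()
  ke <- 2.20 / 3.36
  # end of a 0.5-h 1000 mg/h infusion
  expect_equal(concentration(0.5, d, p),
               (1000 / 2.20) * (1 - exp(-ke * 0.5)), tolerance = 1e-12)
  expect_equal(concentration(0.5, d, p), 126.9, tolerance = 1e-3)
  # washout 2 h after infusion end
  expect_equal(concentration(2.5, d, p),
               concentration(0.5, d, p) * exp(-ke * 2), tolerance = 1e-12)
  expect_equal(concentration(2.5, d, p), 34.3, tolerance = 2e-3)
  # causality
  expect_equal(concentration(c(-1, 0), d, p), c(0, 0))
  d2 <- data.frame(time = 12, amount = 500, duration = 0.5)
  expect_equal(concentration(c(2, 11.9), d2, p), c(0, 0))
})

test_that("kinetics are linear in dose and strictly decreasing after the last infusion", {
  set.seed(41)
  for (rep in 1:5) {
    p <- list(cl = runif(1, 0.5, 4), v = runif(1, 1, 6))
    d <- data.frame(time = c(0, 12, 24), amount = runif(3, 100, 900),
                    duration = 0.5)
    tt <- sort(runif(20, 0, 40))
    d2 <- d; d2$amount <- 2 * d$amount
    expect_equal(concentration(tt, d2, p), 2 * concentration(tt, d, p),
                 tolerance = 1e-12)
    wash <- seq(24.5, 48, by = 0.25)
    expect_true(all(diff(concentration(wash, d, p)) < 0))
  }
})

test_that("analytic steady state equals brute-force superposition of many doses", {
  set.seed(42)
  for (rep in 1:5) {
    p <- list(cl = runif(1, 0.8, 4), v = runif(1, 1.5, 6))
    reg <- regimen(sample(c(50, 75, 100), 1), sample(c(6, 8, 12), 1))
    wt <- runif(1, 8, 13)
    prof <- steady_state_interval(reg, wt, p, resolution = 0.01)
    n_doses <- 60
    doses <- dose_events(reg, wt, n_doses)
    brute <- concentration((n_doses - 1) * reg$interval + prof$time, doses, p)
    expect_lt(max(abs(prof$conc - brute)), 1e-6)
  }
})

test_that("steady-state AUC equals daily dose over clearance", {
  p <- tp_ref()
  reg <- regimen(100, 12)
  expect_equal(ss_auc24(reg, 10.25, p), 1025 / 2.20, tolerance = 1e-12)
  expect_equal(ss_auc24(reg, 10.25, p), 465.9, tolerance = 1e-4)
  # trapezoid AUC over the interval x doses/day within 0.1%
  prof <- steady_state_interval(reg, 10.25, p, resolution = 0.001)
  auc <- sum(diff(prof$time) * (head(prof$conc, -1) + tail(prof$conc, -1)) / 2)
  expect_equal(auc * 2, 465.9091, tolerance = 1e-3)
  # AUC is independent of infusion duration at fixed daily dose
  for (dur in c(0.25, 1, 2)) {
    pr <- steady_state_interval(regimen(100, 12, duration = dur), 10.25, p,
                                resolution = 0.001)
    a <- sum(diff(pr$time) * (head(pr$conc, -1) + tail(pr$conc, -1)) / 2)
    expect_equal(a * 2, 465.9091, tolerance = 1e-3)
  }
})

test_that("with negligible accumulation the steady-state profile is the single-dose profile", {
  # short half-life relative to the interval: ke * tau >> 1
  p <- list(cl = 8, v = 2)                 # ke = 4 /h, tau = 12 h
  reg <- regimen(100, 12)
  prof <- steady_state_interval(reg, 10, p, resolution = 0.01)
  single <- concentration(prof$time, dose_events(reg, 10, 1), p)
  expect_equal(prof$conc[-1], single[-1], tolerance = 1e-10)
})

test_that("regimen objects validate and expand to dose events", {
  expect_error(regimen(100, 7), "divide")
  expect_error(regimen(-10, 12), "positive")
  expect_error(regimen(100, 12, duration = 13), "duration")
  de <- dose_events(regimen(100, 12), 10.25, 4)
  expect_equal(de$time, c(0, 12, 24, 36))
  expect_equal(de$amount, rep(512.5, 4))
  expect_equal(dose_amount(regimen(75, 6), 10), 187.5)
})
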