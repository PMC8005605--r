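test_that("fT>MIC hits its limits and the derived reference value", {
  p <- typical_params(arc_infant_model(), 10.25, 1.25)
  reg <- regimen(100, 12)
  expect_equal(ft_above_mic(reg, 10.25, p, mic = 1e-9), 1)
  expect_equal(ft_above_mic(reg, 10.25, p, mic = 1e4), 0)
  expect_equal(ft_above_mic(reg, 10.25, p, mic = 0.25), 0.804,
               tolerance = 1e-3)
  expect_error(ft_above_mic(reg, 10.25, p, mic = -1), "positive")
  expect_error(ft_above_mic(reg, 10.25, p, 0.25, unbound_fraction = 0),
               "unbound")
})

test_that("closed-form fT>MIC matches a dense-grid oracle", {
  set.seed(101)
  for (rep in 1:20) {
    p <- list(cl = runif(1, 0.5, 5), v = runif(1, 1.5, 6))
    reg <- regimen(sample(c(50, 75, 100), 1), sample(c(6, 8, 12), 1))
    wt <- runif(1, 8, 13)
    mic <- sample(c(0.25, 0.5, 2, 8), 1)
    prof <- steady_state_interval(reg, wt, p, resolution = 0.001)
    oracle <- mean(0.77 * prof$conc[-length(prof$conc)] > mic)
    expect_equal(ft_above_mic(reg, wt, p, mic), oracle, tolerance = 2e-3)
  }
})

test_that("a zero-IIV population attains the target exactly when the typical subject does", {
  m0 <- arc_infant_model()
  m0$omega2 <- c(cl = 0, v = 0)
  pop <- generate_population(200, seed = 111)
  pop$weight[] <- 10.25; pop$age[] <- 1.25
  pta <- simulate_pta(m0, pop, regimen(100, 12), mics = c(0.25, 0.5, 2, 8),
                      seed = 112)
  ft <- ft_above_mic(regimen(100, 12), 10.25,
                     typical_params(m0, 10.25, 1.25), 0.25)
  expect_true(all(pta$attainment %in% c(0, 1)))
  expect_equal(pta$attainment[pta$mic == 0.25], as.numeric(ft >= 0.70))
})

test_that("attainment is monotone in MIC, daily dose, and dosing frequency", {
  m <- arc_infant_model()
  pop <- generate_population(400, seed = 121)
  regs <- list(regimen(50, 12), regimen(75, 12), regimen(100, 12),
               regimen(100, 8), regimen(100, 6))
  pta <- simulate_pta(m, pop, regs, seed = 122)
  # non-increasing along the MIC grid at fixed regimen
  for (r in unique(pta$regimen)) {
    d <- pta[pta$regimen == r, ]
    expect_true(all(diff(d$attainment[order(d$mic)]) <= 0))
  }
  # non-decreasing in daily dose at fixed interval and MIC
  for (mic in unique(pta$mic)) {
    d <- pta[pta$interval == 12 & pta$mic == mic, ]
    expect_true(all(diff(d$attainment[order(d$daily_dose)]) >= -1e-12))
  }
  # shortening the interval at fixed daily dose never hurts this target
  for (mic in unique(pta$mic)) {
    d <- pta[pta$daily_dose == 100 & pta$mic == mic, ]
    expect_true(all(diff(d$attainment[order(-d$interval)]) >= -1e-12))
  }
})

test_that("PTA runs are seed-reproducible and seed-stable", {
  m <- arc_infant_model()
  pop <- generate_population(1000, seed = 131)
  a <- simulate_pta(m, pop, regimen(100, 12), seed = 132)
  b <- simulate_pta(m, pop, regimen(100, 12), seed = 132)
  expect_identical(a, b)
  c <- simulate_pta(m, pop, regimen(100, 12), seed = 133)
  # 95% band for the difference of two independent binomial proportions
  band <- qnorm(0.975) * sqrt(2 * 0.25 / 1000)
  expect_lt(max(abs(a$attainment - c$attainment)), band)
})

test_that("regimen recommendation picks the lowest-burden adequate regimen", {
  tab <- expand.grid(daily_dose = c(50, 100), interval = c(12, 8),
                     mic = c(0.5, 2, 8))
  tab$regimen <- sprintf("%g mg/kg/day q%gh", tab$daily_dose, tab$interval)
  tab$n <- 1000; tab$seed <- 1
  att <- c(
    "50 q12 0.5" = 0.60, "100 q12 0.5" = 0.75,
    "50 q8 0.5" = 0.80, "100 q8 0.5" = 0.90,
    "50 q12 2" = 0.30, "100 q12 2" = 0.55,
    "50 q8 2" = 0.72, "100 q8 2" = 0.85,
    "50 q12 8" = 0.05, "100 q12 8" = 0.10,
    "50 q8 8" = 0.15, "100 q8 8" = 0.25)
  tab$attainment <- att[sprintf("%g q%g %g", tab$daily_dose, tab$interval,
                                tab$mic)]
  tab$adequate <- tab$attainment >= 0.7
  class(tab) <- c("pta_result", "data.frame")
  rec <- recommend_regimens(tab)
  # q12h wins while adequate even though q8h at a lower dose also qualifies
  expect_equal(rec$recommended[rec$mic == 0.5], "100 mg/kg/day q12h")
  # frequency escalates only when no q12h regimen is adequate, and the
  # lowest adequate dose at the new frequency is picked
  expect_equal(rec$recommended[rec$mic == 2], "50 mg/kg/day q8h")
  expect_equal(rec$recommended[rec$mic == 8], "none adequate")
  expect_equal(rec$attainment[rec$mic == 8], 0.25)
})
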