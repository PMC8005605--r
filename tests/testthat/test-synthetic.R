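test_that("every draw respects the covariate truncation bounds and the ARC filter", {
  pop <- generate_population(2000, seed = 201)
  expect_true(all(pop$weight >= 8.00 & pop$weight <= 13.00))
  expect_true(all(pop$age >= 0.35 & pop$age <= 1.86))
  expect_true(all(pop$scr >= 10 & pop$scr <= 26))
  expect_true(all(pop$egfr >= 130))
  expect_true(all(pop$arc))
  expect_equal(sum(pop$sex == 0), sum(pop$sex == 1), tolerance = 0)
})

test_that("sample moments match the generating truncated normals", {
  pop <- generate_population(10000, seed = 202)
  expect_equal(mean(pop$weight),
               trunc_norm_mean(10.33, 1.57, 8, 13), tolerance = 0.05 / 10.33)
  expect_equal(mean(pop$age),
               trunc_norm_mean(1.20, 0.43, 0.35, 1.86),
               tolerance = 0.02 / 1.20)
  expect_gt(cor(pop$weight, pop$age), 0.4)
})

test_that("weight and age pass a KS test against their truncated normals", {
  pop <- generate_population(2000, seed = 203)
  p_w <- suppressWarnings(ks.test(
    pop$weight, function(x) ptrunc_norm(x, 10.33, 1.57, 8, 13))$p.value)
  p_a <- suppressWarnings(ks.test(
    pop$age, function(x) ptrunc_norm(x, 1.20, 0.43, 0.35, 1.86))$p.value)
  expect_gt(p_w, 0.01)
  expect_gt(p_a, 0.01)
})

test_that("an infeasible covariate specification is rejected", {
  expect_error(population_spec(weight_mean = 10, weight_sd = 0.1,
                               weight_range = c(20, 25)),
               "infeasible")
  expect_error(population_spec(wt_age_cor = 1.2), "wt_age_cor")
})

test_that("trial simulation is deterministic given the seed", {
  pop <- generate_population(20, seed = 204)
  m <- arc_infant_model()
  ds1 <- simulate_trial(pop, m, seed = 205)
  ds2 <- simulate_trial(pop, m, seed = 205)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds1, f1); write_dataset(ds2, f2)
  expect_identical(readLines(f1), readLines(f2))
  ds3 <- simulate_trial(pop, m, seed = 206)
  expect_false(identical(ds1$events$dv, ds3$events$dv))
})

test_that("a noiseless trial reproduces the typical predictions exactly", {
  m0 <- arc_infant_model()
  m0$omega2 <- c(cl = 0, v = 0)
  m0$sigma2 <- 1e-30
  pop <- generate_population(5, seed = 207)
  ds <- simulate_trial(pop, m0, seed = 208)
  tv <- typical_params(m0, ds$subjects$weight, ds$subjects$age)
  ev <- ds$events
  for (i in seq_len(nrow(ds$subjects))) {
    d <- ev[ev$id == ds$subjects$id[i], ]
    obs <- d[d$evid == 0, ]; dose <- d[d$evid == 1, ]
    pred <- concentration(obs$time,
                          data.frame(time = dose$time, amount = dose$amt,
                                     duration = dose$dur),
                          list(cl = tv$cl[i], v = tv$v[i]))
    expect_equal(obs$dv, pred, tolerance = 1e-9)
  }
})

test_that("the default design emulates the sparse 20-infant study", {
  m <- arc_infant_model()
  n_obs <- conc_min <- conc_max <- numeric(15)
  for (s in 1:15) {
    pop <- generate_population(20, seed = 300 + s)
    ds <- simulate_trial(pop, m, seed = 400 + s)
    n_obs[s] <- sum(ds$subjects$n_obs)
    conc_min[s] <- min(ds$events$dv, na.rm = TRUE)
    conc_max[s] <- max(ds$events$dv, na.rm = TRUE)
  }
  # around 36 samples per 20 subjects on average
  expect_gt(mean(n_obs), 32)
  expect_lt(mean(n_obs), 40)
  # concentrations live in (roughly) the observed envelope
  expect_true(all(conc_min >= 0.03))
  expect_lt(median(conc_min), 2)
  expect_gt(median(conc_max), 50)
  expect_true(all(conc_max < 500))
})

test_that("generated datasets pass validation without errors", {
  for (s in 1:5) {
    pop <- generate_population(20, seed = 500 + s)
    ds <- simulate_trial(pop, arc_infant_model(), seed = 600 + s)
    path <- withr::local_tempfile(fileext = ".csv")
    write_dataset(ds, path)
    expect_no_error(read_dataset(path))
  }
})
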