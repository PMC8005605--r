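test_that("with vanishing IIV the OFV reduces to the naive -2 log likelihood", {
  ds <- tiny_dataset()
  m <- pop_model(theta = c(cl = 2.2, v = 3.4), omega2 = c(cl = 0, v = 0),
                 sigma2 = 0.05)
  expect_equal(as.numeric(ofv_foce(ds, m)), naive_m2ll(ds, m),
               tolerance = 1e-8)
})

test_that("FOCE matches adaptive Gauss-Hermite quadrature on tiny instances", {
  # single subject, single observation near the typical curve
  m <- pop_model(theta = c(cl = 2.0, v = 3.2),
                 omega2 = c(cl = 0.08, v = 0.06), sigma2 = 0.05)
  tv <- typical_params(m, 10, 1.2)
  pred <- concentration(2, data.frame(time = 0, amount = 500,
                                      duration = 0.5), tv)
  df <- data.frame(ID = 1, TIME = c(0, 2), AMT = c(500, NA),
                   DUR = c(0.5, NA), DV = c(NA, pred * exp(0.15)),
                   EVID = c(1, 0), MDV = c(1, 0), WT = 10, AGE = 1.2,
                   SEX = 0, SCR = 18, HT = 76)
  ds1 <- pk_dataset(df)
  expect_lt(abs(as.numeric(ofv_foce(ds1, m)) - ofv_agq(ds1, m)), 0.05)

  # a few random parameter sets on the 2-subject instance
  set.seed(51)
  ds <- tiny_dataset()
  for (rep in 1:5) {
    mr <- pop_model(theta = c(cl = runif(1, 1.5, 3.0), v = runif(1, 2.5, 4.5)),
                    omega2 = c(cl = runif(1, 0.03, 0.10),
                               v = runif(1, 0.03, 0.10)),
                    sigma2 = runif(1, 0.02, 0.08))
    expect_lt(abs(as.numeric(ofv_foce(ds, mr)) - ofv_agq(ds, mr)), 0.1)
  }
})

test_that("independent subjects contribute additively to the OFV", {
  ds <- tiny_dataset()
  m <- arc_infant_model()
  ev <- tiny_events()
  dup <- rbind(ev, transform(ev, ID = ID + 10))
  ds_dup <- pk_dataset(dup)
  expect_equal(as.numeric(ofv_foce(ds_dup, m)),
               2 * as.numeric(ofv_foce(ds, m)), tolerance = 1e-8)
})

test_that("the OFV is invariant to subject relabelling and time-origin shifts", {
  m <- arc_infant_model()
  ds <- study_dataset(seed = 31)
  ev <- ds$events
  # relabel subjects in reverse order
  relab <- ev
  relab$id <- max(ev$id) + 1 - ev$id
  df <- data.frame(ID = relab$id, TIME = relab$time, AMT = relab$amt,
                   DUR = relab$dur, DV = relab$dv, EVID = relab$evid,
                   MDV = relab$mdv, WT = relab$weight, AGE = relab$age,
                   SEX = relab$sex, SCR = relab$scr, HT = relab$height)
  expect_equal(as.numeric(ofv_foce(pk_dataset(df), m)),
               as.numeric(ofv_foce(ds, m)), tolerance = 1e-8)
  # shift every subject's clock by +5 h
  df2 <- data.frame(ID = ev$id, TIME = ev$time + 5, AMT = ev$amt,
                    DUR = ev$dur, DV = ev$dv, EVID = ev$evid,
                    MDV = ev$mdv, WT = ev$weight, AGE = ev$age,
                    SEX = ev$sex, SCR = ev$scr, HT = ev$height)
  expect_equal(as.numeric(ofv_foce(pk_dataset(df2), m)),
               as.numeric(ofv_foce(ds, m)), tolerance = 1e-8)
})

test_that("empirical-Bayes estimates behave at the edges and recover known eta", {
  m <- arc_infant_model()
  # subject with doses but no observations sits at the prior mode
  ev <- tiny_events()
  ev_no_obs <- rbind(ev, data.frame(ID = 3, TIME = 0, AMT = 450, DUR = 0.5,
                                    DV = NA, EVID = 1, MDV = 1, WT = 9,
                                    AGE = 0.8, SEX = 0, SCR = 15, HT = 72))
  eb <- empirical_bayes(pk_dataset(ev_no_obs), m)
  expect_equal(unlist(eb[eb$id == 3, c("eta_cl", "eta_v")]),
               c(eta_cl = 0, eta_v = 0))

  # observations exactly on the typical curve pull eta to 0 as sigma -> 0
  pop1 <- generate_population(2, seed = 61)
  m_small_sig <- m; m_small_sig$sigma2 <- 1e-8
  m_zero <- m; m_zero$omega2 <- c(cl = 0, v = 0); m_zero$sigma2 <- 1e-12
  ds_exact <- simulate_trial(pop1, m_zero, seed = 62, lloq = 0)
  eb2 <- empirical_bayes(ds_exact, m_small_sig)
  expect_lt(max(abs(c(eb2$eta_cl, eb2$eta_v))), 1e-3)

  # dense noiseless data recover a known eta
  true_eta <- c(0.31, -0.22)
  pop <- generate_population(1, seed = 63)
  tv <- typical_params(m, pop$weight, pop$age)
  doses <- dose_events(regimen(100, 12), pop$weight, 4)
  tt <- as.vector(outer(c(0.5, 1, 2, 4, 6, 8), c(0, 12, 24, 36), "+"))
  conc <- concentration(tt, doses,
                        individual_params(tv, true_eta[1], true_eta[2]))
  df <- rbind(
    data.frame(ID = 1, TIME = doses$time, AMT = doses$amount, DUR = 0.5,
               DV = NA, EVID = 1, MDV = 1),
    data.frame(ID = 1, TIME = tt, AMT = NA, DUR = NA, DV = conc,
               EVID = 0, MDV = 0))
  df$WT <- pop$weight; df$AGE <- pop$age; df$SEX <- pop$sex
  df$SCR <- pop$scr; df$HT <- pop$height
  m_dense <- m; m_dense$sigma2 <- 1e-8
  eb3 <- empirical_bayes(pk_dataset(df, lloq = 0), m_dense)
  expect_equal(c(eb3$eta_cl, eb3$eta_v), true_eta, tolerance = 1e-3)
})

test_that("shrinkage is near-total for uninformative data and small for rich data", {
  m <- arc_infant_model()
  # near-noiseless observations on the typical curve: eta-hat ~ 0, full shrinkage
  pop <- generate_population(10, seed = 71)
  m_zero <- m; m_zero$omega2 <- c(cl = 0, v = 0); m_zero$sigma2 <- 1e-12
  ds_typ <- simulate_trial(pop, m_zero, seed = 72)
  m_eval <- m; m_eval$sigma2 <- 1e-6
  shr <- shrinkage(ds_typ, m_eval)
  expect_gt(min(shr$eta), 99)

  # rich data from the full model: little shrinkage
  pop2 <- generate_population(80, seed = 73)
  ds_rich <- simulate_trial(pop2, m, rich_design(), seed = 74)
  shr2 <- shrinkage(ds_rich, m)
  expect_lt(max(shr2$eta), 30)
  expect_true(all(shr2$eta > -20))
})

test_that("CWRES is calibrated under the truth and detects gross misfit", {
  m <- arc_infant_model()
  pop <- generate_population(90, seed = 81)
  ds <- simulate_trial(pop, m, rich_design(), seed = 82)  # 540 observations
  cw <- cwres(ds, m)
  expect_gte(nrow(cw), 500)
  expect_lt(abs(mean(cw$cwres)), 0.15)
  expect_gt(sd(cw$cwres), 0.8)
  expect_lt(sd(cw$cwres), 1.2)
  # study-scale residuals mostly inside +/- 2
  ds20 <- study_dataset(seed = 83)
  cw20 <- cwres(ds20, m)
  expect_gte(mean(abs(cw20$cwres) <= 2), 0.9)
  # halving CL in the evaluated model biases the residuals
  m_bad <- m; m_bad$theta[["cl"]] <- m$theta[["cl"]] / 2
  cw_bad <- cwres(ds, m_bad)
  expect_gt(abs(mean(cw_bad$cwres)), 0.5)
})

test_that("noiseless data identify the fixed effects to within 0.1%", {
  truth <- arc_infant_model()
  truth$omega2 <- c(cl = 0, v = 0)
  truth$sigma2 <- 1e-8                     # sigma = 1e-4
  pop <- generate_population(12, seed = 91)
  ds <- simulate_trial(pop, truth, rich_design(), seed = 92)
  init <- truth
  init$theta <- c(cl = 1.8, v = 4.0)
  init$covariates[[1]]$est <- 0.4
  init$omega2 <- c(cl = 1e-4, v = 1e-4)
  init$sigma2 <- 1e-6
  fit <- fit_foce(ds, init, compute_se = FALSE)
  expect_equal(unname(fit$estimates["theta_cl"]), 2.20, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["theta_v"]), 3.36, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["beta_cl_age"]), 0.662,
               tolerance = 2e-3)
})

test_that("theta_cl recovery improves with the number of subjects", {
  truth <- arc_infant_model()
  est_at <- function(n, seed) {
    pop <- generate_population(n, seed = seed)
    ds <- simulate_trial(pop, truth,
                         sampling_design(c(0.2, 0.4, 0.4)), seed = seed + 1)
    fit <- fit_foce(ds, truth, compute_se = FALSE)
    unname(fit$estimates["theta_cl"])
  }
  seeds <- 100 + 7 * (1:12)
  e20 <- vapply(seeds, function(s) est_at(20, s), numeric(1))
  e200 <- vapply(seeds, function(s) est_at(200, s), numeric(1))
  rmse <- function(x) sqrt(mean((x - 2.20)^2))
  expect_lt(rmse(e200), rmse(e20))
})
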