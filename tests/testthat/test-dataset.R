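test_that("a small NONMEM-style CSV reads into a validated dataset", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tiny_events(), path, row.names = FALSE, na = ".")
  ds <- read_dataset(path)
  expect_s3_class(ds, "pk_dataset")
  expect_equal(nrow(ds$subjects), 2)
  expect_equal(sum(ds$subjects$n_obs), 4)
  expect_equal(sum(ds$subjects$n_dose), 2)
  expect_false(any(ds$events$below_lloq))
})

test_that("schema and validation errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("", path)
  expect_error(read_dataset(path), "schema")

  ev <- tiny_events()
  expect_error(pk_dataset(ev[, setdiff(names(ev), "WT")]), "WT")

  ev2 <- tiny_events(); ev2$TIME[2] <- -1
  expect_error(pk_dataset(ev2), "negative TIME.*2")

  ev3 <- tiny_events(); ev3$AMT[1] <- -500
  expect_error(pk_dataset(ev3), "AMT")

  # observation before any dose
  ev4 <- tiny_events(); ev4$TIME[1] <- 2
  expect_error(pk_dataset(ev4), "before any dose")
})

test_that("column_map renames non-standard headers", {
  ev <- tiny_events()
  names(ev)[names(ev) == "WT"] <- "BODYWEIGHT"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(ev, path, row.names = FALSE, na = ".")
  expect_error(read_dataset(path), "WT")
  ds <- read_dataset(path, column_map = c(WT = "BODYWEIGHT"))
  expect_equal(ds$subjects$weight, c(10, 11))
})

test_that("write_dataset / read_dataset round-trip a study-scale dataset", {
  ds <- study_dataset(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  ds2 <- read_dataset(path)
  for (col in c("id", "time", "amt", "dur", "dv", "evid", "mdv",
                "weight", "age", "sex", "scr", "height"))
    expect_equal(ds2$events[[col]], ds$events[[col]], tolerance = 1e-10)
  expect_equal(ds2$subjects, ds$subjects, tolerance = 1e-10)
})

test_that("Schwartz eGFR matches hand calculations and scales correctly", {
  expect_equal(compute_egfr(scr = 20, height = 80), 146.0, tolerance = 1e-3)
  expect_equal(compute_egfr(scr = 10, height = 75), 273.8, tolerance = 1e-3)
  # Scr = 88.4 umol/L is exactly 1 mg/dL
  expect_equal(compute_egfr(scr = 88.4, height = 100), 41.3)
  # homogeneity
  scr <- c(12, 18, 25); ht <- c(70, 78, 86)
  expect_equal(compute_egfr(scr, 2 * ht), 2 * compute_egfr(scr, ht))
  expect_equal(compute_egfr(2 * scr, ht), compute_egfr(scr, ht) / 2)
  expect_error(compute_egfr(0, 80), "positive")
  expect_error(compute_egfr(20, -1), "positive")
})

test_that("ARC classification uses an inclusive 130 threshold, monotonely", {
  expect_true(classify_arc(130.0))
  expect_false(classify_arc(129.9))
  expect_true(classify_arc(197))
  g <- seq(50, 400, by = 10)
  expect_true(all(diff(as.integer(classify_arc(g))) >= 0))
  expect_error(classify_arc(0), "positive")
})

test_that("observations below the LLOQ are flagged and excluded", {
  ev <- tiny_events()
  ev$DV[2] <- 0.01                         # below 0.03 mg/L
  expect_warning(ds <- pk_dataset(ev), "LLOQ")
  expect_equal(sum(ds$events$below_lloq), 1)
  split <- cefapk:::dataset_split(ds)
  expect_equal(length(split[[1]]$dv), 1)   # excluded from estimation view
})
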