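#' Schwartz estimated glomerular filtration rate
#'
#' Bedside (single-constant) Schwartz formula,
#' `eGFR = k * height / Scr`, with serum creatinine converted from umol/L
#' to mg/dL (factor 88.4) and `k = 0.413` by default. The constant is a
#' parameter so age-banded Schwartz variants can be substituted.
#'
#' @param scr serum creatinine, umol/L.
#' @param height height, cm.
#' @param k Schwartz constant (default 0.413).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' compute_egfr(scr = 20, height = 80)  # 146.0
#' @export
compute_egfr <- function(scr, height, k = 0.413) {
  if (any(scr <= 0) || any(height <= 0))
    stop("scr and height must be positive")
  k * height / (scr / 88.4)
}

#' Augmented renal clearance classification
#'
#' ARC is defined as eGFR at or above 130 mL/min/1.73 m^2 (inclusive).
#'
#' @param egfr estimated GFR, mL/min/1.73 m^2.
#' @return logical.
#' @export
classify_arc <- function(egfr) {
  if (any(egfr <= 0)) stop("egfr must be positive")
  egfr >= 130
}

std_cols <- c(id = "ID", time = "TIME", amt = "AMT", dur = "DUR", dv = "DV",
              evid = "EVID", mdv = "MDV", weight = "WT", age = "AGE",
              sex = "SEX", scr = "SCR", height = "HT")
required_cols <- c("id", "time", "amt", "dv", "evid", "weight", "age",
                   "sex", "scr")

#' Longitudinal PK dataset
#'
#' Builds a validated dataset from a long event table in NONMEM dialect:
#' one row per event, `EVID = 1` for doses (with `AMT` mg and infusion
#' `DUR` h) and `EVID = 0` for observations (with `DV` mg/L). Baseline
#' covariates (`WT` kg, `AGE` years, `SEX` 0 = male / 1 = female, `SCR`
#' umol/L, optional `HT` cm) repeat on every row of a subject. Time is in
#' hours from each subject's first dose.
#'
#' Validation enforces: required columns present, positive dose amounts and
#' durations, non-negative times, at least one dose before a subject's first
#' observation, and positive covariates. Rows are ordered by subject and
#' time. Observations below the assay lower limit of quantification
#' (`lloq`, default 0.03 mg/L) are flagged `below_lloq` and excluded from
#' estimation. Per-dose amounts far from the nominal daily dose implied by
#' the design raise warnings, never silent corrections.
#'
#' @param events data.frame in the dialect above (lower- or upper-case
#'   column names).
#' @param lloq assay lower limit of quantification, mg/L.
#' @return an object of class `pk_dataset`: list with `events` (normalized
#'   event table) and `subjects` (one row per subject: covariates plus
#'   derived `egfr` and `arc` when height is available).
#' @export
pk_dataset <- function(events, lloq = 0.03) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) stop("schema error: dataset has no rows")
  nm <- toupper(names(events))
  names(events) <- nm
  missing_req <- setdiff(unname(std_cols[required_cols]), nm)
  if (length(missing_req) > 0)
    stop("schema error: missing required column(s) ",
         paste(missing_req, collapse = ", "))
  ev <- data.frame(id = events$ID)
  for (f in setdiff(names(std_cols), "id")) {
    col <- std_cols[[f]]
    ev[[f]] <- if (col %in% nm) suppressWarnings(as.numeric(
      replace(events[[col]], events[[col]] %in% c(".", ""), NA))) else NA_real_
  }
  if (all(is.na(ev$mdv))) ev$mdv <- ifelse(ev$evid == 0, 0, 1)
  if (all(is.na(ev$dur))) ev$dur[ev$evid == 1] <- 0.5

  bad <- which(ev$time < 0)
  if (length(bad) > 0)
    stop("validation error: negative TIME at row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(ev$evid == 1 & (is.na(ev$amt) | ev$amt <= 0))
  if (length(bad) > 0)
    stop("validation error: missing or non-positive AMT at dose row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(ev$evid == 1 & (is.na(ev$dur) | ev$dur <= 0))
  if (length(bad) > 0)
    stop("validation error: missing or non-positive DUR at dose row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(ev$evid == 0 & ev$mdv == 0 & (is.na(ev$dv) | ev$dv < 0))
  if (length(bad) > 0)
    stop("validation error: missing or negative DV at observation row(s) ",
         paste(bad, collapse = ", "))

  ev <- ev[order(ev$id, ev$time, -ev$evid), , drop = FALSE]
  rownames(ev) <- NULL
  ev$below_lloq <- ev$evid == 0 & ev$mdv == 0 & !is.na(ev$dv) & ev$dv < lloq
  if (any(ev$below_lloq))
    warning(sum(ev$below_lloq), " observation(s) below the LLOQ (",
            lloq, " mg/L) flagged and excluded from estimation")

  subs <- do.call(rbind, lapply(split(ev, ev$id), function(d) {
    for (f in c("weight", "age", "sex", "scr")) {
      if (all(is.na(d[[f]])))
        stop("validation error: subject ", d$id[1], " has no ", toupper(f))
      if (length(unique(stats::na.omit(d[[f]]))) > 1)
        warning("subject ", d$id[1], ": time-varying ", toupper(f),
                "; using the first value (covariates are baseline)")
    }
    first <- function(x) stats::na.omit(x)[1]
    obs <- d[d$evid == 0 & d$mdv == 0, , drop = FALSE]
    dose <- d[d$evid == 1, , drop = FALSE]
    if (nrow(obs) > 0 && (nrow(dose) == 0 || min(dose$time) > min(obs$time)))
      stop("validation error: subject ", d$id[1],
           " has observations before any dose")
    data.frame(id = d$id[1], weight = first(d$weight), age = first(d$age),
               sex = first(d$sex), scr = first(d$scr),
               height = if (all(is.na(d$height))) NA_real_ else first(d$height),
               n_dose = nrow(dose), n_obs = nrow(obs))
  }))
  rownames(subs) <- NULL
  if (any(subs$weight <= 0) || any(subs$age <= 0) || any(subs$scr <= 0))
    stop("validation error: non-positive covariate (WT/AGE/SCR)")
  subs$egfr <- ifelse(is.na(subs$height), NA_real_,
                      compute_egfr(subs$scr, pmax(subs$height, 1e-9)))
  subs$arc <- ifelse(is.na(subs$egfr), NA, subs$egfr >= 130)

  dose <- ev[ev$evid == 1, , drop = FALSE]
  mgkg <- dose$amt / subs$weight[match(dose$id, subs$id)]
  if (any(mgkg > 100 | mgkg < 1))
    warning("per-dose amounts outside 1-100 mg/kg detected; check AMT units")

  structure(list(events = ev, subjects = subs, lloq = lloq),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("PK dataset: %d subjects, %d dose events, %d observations",
              nrow(x$subjects), sum(x$subjects$n_dose), sum(x$subjects$n_obs)))
  if (any(x$events$below_lloq))
    cat(sprintf(" (%d below LLOQ)", sum(x$events$below_lloq)))
  cat("\n")
  invisible(x)
}

#' Read / write a PK dataset CSV
#'
#' `read_dataset` reads a NONMEM-style CSV (columns ID, TIME, AMT, DUR, DV,
#' EVID, MDV, WT, AGE, SEX, SCR, HT; `"."` as the missing-data code) and
#' validates it via [pk_dataset()]. `column_map` renames non-standard
#' headers, e.g. `c(WT = "BODYWEIGHT")`. `write_dataset` writes the
#' normalized event table back in the same dialect; the pair round-trips a
#' valid dataset unchanged.
#'
#' @param path CSV file path.
#' @param column_map optional named character vector: standard name ->
#'   column name present in the file.
#' @param lloq assay LLOQ passed to [pk_dataset()].
#' @return `read_dataset`: a `pk_dataset`; `write_dataset`: `path`,
#'   invisibly.
#' @export
read_dataset <- function(path, column_map = NULL, lloq = 0.03) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("schema error: ", conditionMessage(e)))
  if (nrow(raw) == 0 || ncol(raw) <= 1 && all(is.na(raw[[1]])))
    stop("schema error: empty dataset file")
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      j <- match(column_map[[std]], names(raw))
      if (is.na(j)) stop("schema error: mapped column '", column_map[[std]],
                         "' not found")
      names(raw)[j] <- std
    }
  }
  pk_dataset(raw, lloq = lloq)
}

#' @param ds a `pk_dataset`.
#' @rdname read_dataset
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "pk_dataset"))
  ev <- ds$events
  out <- data.frame(ID = ev$id, TIME = ev$time, AMT = ev$amt, DUR = ev$dur,
                    DV = ev$dv, EVID = ev$evid, MDV = ev$mdv, WT = ev$weight,
                    AGE = ev$age, SEX = ev$sex, SCR = ev$scr, HT = ev$height)
  for (j in names(out)) out[[j]][is.na(out[[j]])] <- "."
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: estimation view of a dataset — per-subject dose table and
# quantifiable observations, as plain lists consumed by the FOCE kernel.
dataset_split <- function(ds) {
  stopifnot(inherits(ds, "pk_dataset"))
  lapply(split(ds$events, ds$events$id)[as.character(ds$subjects$id)],
         function(d) {
    obs <- d[d$evid == 0 & d$mdv == 0 & !d$below_lloq, , drop = FALSE]
    dose <- d[d$evid == 1, , drop = FALSE]
    list(id = d$id[1],
         obs_time = obs$time, dv = obs$dv,
         dose_time = dose$time, amt = dose$amt, dur = dose$dur)
  })
}
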