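#' Stepwise covariate selection
#'
#' Forward-selection / backward-deletion search over candidate
#' covariate-parameter pairs, starting from a base model that already
#' carries the fixed allometric weight scaling. In the forward phase the
#' candidate giving the largest OFV reduction is added if the reduction
#' exceeds `forward_threshold` (3.84, chi-square 1 df at p < 0.05; the
#' inequality is strict). From the resulting full model, the backward phase
#' deletes any covariate whose removal raises the OFV by no more than
#' `backward_threshold` (6.635, chi-square 1 df at p < 0.01), removing the
#' least influential first. A candidate whose fit fails is skipped with a
#' warning, never aborting the search.
#'
#' @param ds a [pk_dataset()].
#' @param base a [pop_model()]: the base model (fitted values are a good
#'   starting point but any valid initial values work).
#' @param candidates list of [cov_term()] templates to screen; the default
#'   screens age, eGFR and sex on both CL and V (weight is already in the
#'   base model through allometry). eGFR/sex candidates are dropped with a
#'   warning when the dataset lacks the covariate.
#' @param forward_threshold,backward_threshold OFV change thresholds.
#' @param final_se compute standard errors for the final refit (default
#'   TRUE; disable inside calibration loops).
#' @param control passed to [fit_foce()].
#' @return list of class `covariate_selection`: `model` (selected
#'   [pop_model()]), `fit` (final [fit_foce()] result), `trace`
#'   (data.frame: phase, step, candidate, ofv, delta_ofv, decision).
#' @export
stepwise_select <- function(ds, base,
                            candidates = default_candidates(),
                            forward_threshold = 3.84,
                            backward_threshold = 6.635,
                            final_se = TRUE,
                            control = list()) {
  stopifnot(forward_threshold > 0, backward_threshold > 0)
  if (forward_threshold >= backward_threshold)
    stop("forward threshold must be below the backward threshold")
  have_egfr <- !any(is.na(ds$subjects$egfr))
  keep <- vapply(candidates, function(tm) {
    if (tm$cov == "egfr" && !have_egfr) {
      warning("dropping eGFR candidate: dataset has no height/eGFR")
      return(FALSE)
    }
    TRUE
  }, logical(1))
  candidates <- candidates[keep]

  term_id <- function(tm) paste0(tm$cov, "_on_", tm$param)
  trace <- list()
  note <- function(phase, step, cand, ofv, dofv, decision)
    trace[[length(trace) + 1]] <<-
      data.frame(phase = phase, step = step, candidate = cand, ofv = ofv,
                 delta_ofv = dofv, decision = decision)

  cur_fit <- fit_foce(ds, base, compute_se = FALSE, control = control)
  cur_model <- cur_fit$model
  note("forward", 0L, "(base)", cur_fit$ofv, NA_real_, "start")

  remaining <- candidates
  step <- 0L
  repeat {
    step <- step + 1L
    if (length(remaining) == 0) break
    cand_fits <- vector("list", length(remaining))
    dofv <- rep(NA_real_, length(remaining))
    for (j in seq_along(remaining)) {
      m_try <- add_term(cur_model, remaining[[j]])
      f <- try(fit_foce(ds, m_try, compute_se = FALSE, control = control),
               silent = TRUE)
      if (inherits(f, "try-error")) {
        warning("candidate ", term_id(remaining[[j]]), " failed to fit; skipped")
        next
      }
      cand_fits[[j]] <- f
      dofv[j] <- cur_fit$ofv - f$ofv
    }
    if (all(is.na(dofv))) break
    best <- which.max(dofv)
    accepted <- !is.na(dofv[best]) && dofv[best] > forward_threshold
    for (j in seq_along(remaining))
      note("forward", step, term_id(remaining[[j]]),
           if (is.null(cand_fits[[j]])) NA_real_ else cand_fits[[j]]$ofv,
           dofv[j],
           if (j == best && accepted) "added"
           else if (is.na(dofv[j])) "failed" else "not added")
    if (!accepted) break
    cur_fit <- cand_fits[[best]]
    cur_model <- cur_fit$model
    remaining <- remaining[-best]
  }

  # backward deletion from the full model
  step <- 0L
  repeat {
    sel <- cur_model$covariates
    if (length(sel) == 0) break
    step <- step + 1L
    rises <- rep(NA_real_, length(sel))
    drop_fits <- vector("list", length(sel))
    for (j in seq_along(sel)) {
      m_try <- drop_term(cur_model, j)
      f <- try(fit_foce(ds, m_try, compute_se = FALSE, control = control),
               silent = TRUE)
      if (inherits(f, "try-error")) {
        warning("deletion refit for ", term_id(sel[[j]]), " failed; retained")
        next
      }
      drop_fits[[j]] <- f
      rises[j] <- f$ofv - cur_fit$ofv
    }
    if (all(is.na(rises))) break
    worst <- which.min(rises)
    removed <- !is.na(rises[worst]) && rises[worst] <= backward_threshold
    for (j in seq_along(sel))
      note("backward", step, term_id(sel[[j]]),
           if (is.null(drop_fits[[j]])) NA_real_ else drop_fits[[j]]$ofv,
           rises[j],
           if (j == worst && removed) "removed"
           else if (is.na(rises[j])) "failed" else "retained")
    if (!removed) break
    cur_fit <- drop_fits[[worst]]
    cur_model <- cur_fit$model
  }

  final_fit <- fit_foce(ds, cur_model, compute_se = final_se,
                        control = control)
  structure(list(model = final_fit$model, fit = final_fit,
                 trace = do.call(rbind, trace)),
            class = "covariate_selection")
}

#' @rdname stepwise_select
#' @export
default_candidates <- function() {
  list(cov_term("cl", "age", est = 0.1, ref = 1.25),
       cov_term("v", "age", est = 0.1, ref = 1.25),
       cov_term("cl", "egfr", est = 0.1, ref = 197),
       cov_term("v", "egfr", est = 0.1, ref = 197),
       cov_term("cl", "sex", est = 0.0),
       cov_term("v", "sex", est = 0.0))
}

add_term <- function(model, tm) {
  for (ex in model$covariates)
    if (ex$cov == tm$cov && ex$param == tm$param)
      stop("term already in model")
  model$covariates <- c(model$covariates, list(tm))
  model
}

drop_term <- function(model, j) {
  model$covariates <- model$covariates[-j]
  model
}

#' @export
print.covariate_selection <- function(x, ...) {
  sel <- vapply(x$model$covariates,
                function(tm) paste0(tm$cov, " on ", toupper(tm$param)),
                character(1))
  cat("Stepwise covariate selection\n  selected:",
      if (length(sel)) paste(sel, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  final OFV: %.3f\n", x$fit$ofv))
  invisible(x)
}
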