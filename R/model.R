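#' Population pharmacokinetic model object
#'
#' Constructs the parametric description of the one-compartment population
#' model: fixed effects (typical clearance and volume at the reference
#' covariates, plus any covariate-effect coefficients), diagonal
#' inter-individual variability (IIV) variances on the log scale, and the
#' residual-error model.
#'
#' The structural covariate model is
#' \deqn{CL = \theta_{CL} (WT/WT_{ref})^{0.75} \prod_j f_j(cov_j),\qquad
#'       V  = \theta_V (WT/WT_{ref})^{1} \prod_j f_j(cov_j)}
#' with allometric weight exponents fixed at 0.75 (CL) and 1 (V), and
#' additional screened covariate effects supplied as [cov_term()] objects
#' (power functions of normalized continuous covariates, or a proportional
#' shift for sex). Individual parameters are lognormal:
#' \eqn{CL_i = CL \cdot e^{\eta_{CL,i}}}, \eqn{\eta \sim N(0, \omega^2)}.
#'
#' @param theta named numeric: `cl` (L/h) and `v` (L), typical values at the
#'   reference covariates. Must be positive.
#' @param covariates list of [cov_term()] covariate effects beyond the fixed
#'   allometric weight scaling.
#' @param omega2 named numeric: IIV variances `cl`, `v` (log scale, >= 0).
#' @param sigma2 residual variance. For the default `"exponential"` error
#'   model this is the variance of a Gaussian on log concentration.
#' @param error residual-error form: `"exponential"` (default), `"additive"`,
#'   or `"combined"`; for `"combined"`, `sigma2` has elements `prop` and
#'   `add` (variance scale).
#' @param ref_weight,ref_age reference covariates (kg, years) used to
#'   normalize weight and age; defaults are the cohort medians 10.25 kg and
#'   1.25 years.
#' @param allo_cl,allo_v fixed allometric weight exponents for CL and V.
#' @return an object of class `pop_model`.
#' @seealso [arc_infant_model()] for the final estimated parameter set,
#'   [typical_params()], [individual_params()].
#' @export
pop_model <- function(theta = c(cl = 2.20, v = 3.36),
                      covariates = list(),
                      omega2 = c(cl = 0.0, v = 0.0),
                      sigma2 = 0.05,
                      error = c("exponential", "additive", "combined"),
                      ref_weight = 10.25, ref_age = 1.25,
                      allo_cl = 0.75, allo_v = 1) {
  error <- match.arg(error)
  theta <- unlist(theta)
  if (!all(c("cl", "v") %in% names(theta)))
    stop("`theta` must have elements 'cl' and 'v'")
  if (any(theta[c("cl", "v")] <= 0)) stop("typical CL and V must be positive")
  omega2 <- unlist(omega2)
  if (!all(c("cl", "v") %in% names(omega2)))
    stop("`omega2` must have elements 'cl' and 'v'")
  if (any(omega2 < 0)) stop("IIV variances must be non-negative")
  if (error == "combined") {
    sigma2 <- unlist(sigma2)
    if (!all(c("prop", "add") %in% names(sigma2)))
      stop("combined error needs sigma2 = c(prop = ..., add = ...)")
    if (any(sigma2 < 0) || sum(sigma2) == 0) stop("invalid sigma2")
  } else {
    sigma2 <- as.numeric(sigma2)[1]
    if (sigma2 <= 0) stop("sigma2 must be positive")
  }
  if (ref_weight <= 0 || ref_age <= 0) stop("reference covariates must be positive")
  stopifnot(is.list(covariates))
  for (tm in covariates) {
    if (!inherits(tm, "cov_term")) stop("covariates must be built with cov_term()")
  }
  structure(
    list(theta = theta[c("cl", "v")], covariates = covariates,
         omega2 = omega2[c("cl", "v")], sigma2 = sigma2, error = error,
         ref_weight = ref_weight, ref_age = ref_age,
         allo_cl = allo_cl, allo_v = allo_v),
    class = "pop_model")
}

#' Covariate-effect term
#'
#' One screened covariate effect on a structural parameter. Continuous
#' covariates (age, eGFR, weight) use a power function of the covariate
#' normalized by a reference value, `(x/ref)^est`; sex uses a proportional
#' shift, `1 + est * I(female)`.
#'
#' @param param `"cl"` or `"v"`.
#' @param cov `"age"`, `"egfr"`, `"weight"`, or `"sex"`.
#' @param est effect coefficient (power exponent, or fractional shift).
#' @param ref reference value for normalization (ignored for sex).
#' @param form `"power"` or `"linear"`; defaults to `"linear"` for sex and
#'   `"power"` otherwise.
#' @return an object of class `cov_term`.
#' @export
cov_term <- function(param, cov, est = 0, ref = NA_real_,
                     form = if (cov == "sex") "linear" else "power") {
  param <- match.arg(param, c("cl", "v"))
  cov <- match.arg(cov, c("age", "egfr", "weight", "sex"))
  form <- match.arg(form, c("power", "linear"))
  if (form == "power" && (is.na(ref) || ref <= 0))
    stop("power terms need a positive reference value")
  structure(list(param = param, cov = cov, est = est, ref = ref, form = form),
            class = "cov_term")
}

#' Final ARC-infant cefathiamidine model
#'
#' The estimated population model for intravenous cefathiamidine in infants
#' with augmented renal clearance: typical clearance 2.20 L/h and volume
#' 3.36 L at the reference covariates (10.25 kg, 1.25 years), allometric
#' weight exponents fixed at 0.75/1, an age power function on clearance with
#' exponent 0.662, IIV of 25.6% (CL) and 22.4% (V), and an exponential
#' residual error of 22.6%.
#'
#' @return a [pop_model()] object.
#' @export
arc_infant_model <- function() {
  pop_model(theta = c(cl = 2.20, v = 3.36),
            covariates = list(cov_term("cl", "age", est = 0.662, ref = 1.25)),
            omega2 = c(cl = 0.256^2, v = 0.224^2),
            sigma2 = 0.226^2,
            error = "exponential",
            ref_weight = 10.25, ref_age = 1.25)
}

#' @export
print.pop_model <- function(x, ...) {
  cat("One-compartment population PK model\n")
  cat(sprintf("  CL: %.4g L/h x (WT/%.4g)^%.3g", x$theta["cl"], x$ref_weight, x$allo_cl))
  for (tm in x$covariates) if (tm$param == "cl") cat(" x", format_term(tm))
  cat(sprintf("\n  V : %.4g L   x (WT/%.4g)^%.3g", x$theta["v"], x$ref_weight, x$allo_v))
  for (tm in x$covariates) if (tm$param == "v") cat(" x", format_term(tm))
  cat(sprintf("\n  IIV (CV%%): CL %.1f, V %.1f   residual (%s): %s\n",
              100 * sqrt(x$omega2["cl"]), 100 * sqrt(x$omega2["v"]), x$error,
              paste(signif(sqrt(x$sigma2), 3), collapse = "/")))
  invisible(x)
}

format_term <- function(tm) {
  if (tm$form == "power") sprintf("(%s/%.4g)^%.3g", toupper(tm$cov), tm$ref, tm$est)
  else sprintf("(1 + %.3g*%s)", tm$est, toupper(tm$cov))
}

#' Typical (population) individual parameters
#'
#' Evaluates the fixed-effects covariate model at given covariates: the
#' typical clearance and volume for a subject of that weight and age (and,
#' if the model includes them, eGFR/sex effects).
#'
#' @param model a [pop_model()].
#' @param weight body weight, kg (vectorized).
#' @param age age, years (vectorized).
#' @param egfr,sex optional covariates; `sex` coded 0 = male, 1 = female.
#'   Required only when the model contains a matching covariate term.
#' @return a data.frame with columns `cl` (L/h), `v` (L), `ke` (1/h = cl/v).
#' @examples
#' typical_params(arc_infant_model(), weight = 10.25, age = 1.25)
#' @export
typical_params <- function(model, weight, age, egfr = NULL, sex = NULL) {
  stopifnot(inherits(model, "pop_model"))
  if (any(weight <= 0) || any(age <= 0))
    stop("weight and age must be positive")
  n <- max(length(weight), length(age))
  weight <- rep_len(weight, n); age <- rep_len(age, n)
  cl <- model$theta[["cl"]] * (weight / model$ref_weight)^model$allo_cl
  v  <- model$theta[["v"]]  * (weight / model$ref_weight)^model$allo_v
  covs <- list(age = age, egfr = egfr, weight = weight, sex = sex)
  for (tm in model$covariates) {
    x <- covs[[tm$cov]]
    if (is.null(x)) stop(sprintf("model needs covariate '%s'", tm$cov))
    if (tm$form == "power") {
      if (any(x <= 0)) stop(sprintf("covariate '%s' must be positive", tm$cov))
      f <- (x / tm$ref)^tm$est
    } else {
      f <- 1 + tm$est * x
      if (any(f <= 0)) stop(sprintf("linear term on '%s' gives non-positive factor", tm$cov))
    }
    if (tm$param == "cl") cl <- cl * f else v <- v * f
  }
  data.frame(cl = unname(cl), v = unname(v), ke = unname(cl / v))
}

#' Individual parameters from random effects
#'
#' Applies lognormal inter-individual variability to typical parameters:
#' `cl_i = cl * exp(eta_cl)`, `v_i = v * exp(eta_v)`.
#'
#' @param typical data.frame with columns `cl`, `v` (from [typical_params()]).
#' @param eta_cl,eta_v random effects (log scale), recycled.
#' @return data.frame with columns `cl`, `v`, `ke`.
#' @export
individual_params <- function(typical, eta_cl = 0, eta_v = 0) {
  cl <- typical$cl * exp(eta_cl)
  v <- typical$v * exp(eta_v)
  data.frame(cl = cl, v = v, ke = cl / v)
}

#' Serialize a model to / from YAML
#'
#' Writes the model parameters as a flat key:value YAML file
#' (`theta1`, `theta2`, covariate coefficients such as `theta3` for the age
#' exponent on CL, `omega2_cl`, `omega2_v`, `sigma2`, `ref_weight`,
#' `ref_age`), and reads it back.
#'
#' @param model a [pop_model()].
#' @param path file path.
#' @return `read_model_yaml` returns a [pop_model()]; `write_model_yaml`
#'   returns `path` invisibly.
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "pop_model"))
  x <- list(theta1 = unname(model$theta[["cl"]]),
            theta2 = unname(model$theta[["v"]]),
            omega2_cl = unname(model$omega2[["cl"]]),
            omega2_v = unname(model$omega2[["v"]]),
            error = model$error,
            ref_weight = model$ref_weight, ref_age = model$ref_age,
            allo_cl = model$allo_cl, allo_v = model$allo_v)
  if (model$error == "combined") {
    x$sigma2_prop <- unname(model$sigma2[["prop"]])
    x$sigma2_add <- unname(model$sigma2[["add"]])
  } else x$sigma2 <- unname(model$sigma2)
  x$covariates <- lapply(model$covariates, function(tm)
    list(param = tm$param, cov = tm$cov, est = tm$est,
         ref = if (is.na(tm$ref)) NULL else tm$ref, form = tm$form))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  covs <- lapply(x$covariates, function(tm)
    cov_term(tm$param, tm$cov, est = tm$est,
             ref = if (is.null(tm$ref)) NA_real_ else tm$ref, form = tm$form))
  sigma2 <- if (identical(x$error, "combined"))
    c(prop = x$sigma2_prop, add = x$sigma2_add) else x$sigma2
  pop_model(theta = c(cl = x$theta1, v = x$theta2), covariates = covs,
            omega2 = c(cl = x$omega2_cl, v = x$omega2_v), sigma2 = sigma2,
            error = x$error, ref_weight = x$ref_weight, ref_age = x$ref_age,
            allo_cl = x$allo_cl, allo_v = x$allo_v)
}
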