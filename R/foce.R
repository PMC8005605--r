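#' @useDynLib cefapk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim qnorm pnorm rnorm runif quantile sd median
#'   na.omit setNames
NULL

# --- parameter packing ------------------------------------------------------

# Free parameters, transformed for unconstrained optimization:
# log(theta_cl), log(theta_v), covariate coefficients (natural scale),
# log(omega2_cl), log(omega2_v), log residual variance(s).
pack_params <- function(model) {
  p <- c(lth_cl = log(unname(model$theta[["cl"]])),
         lth_v = log(unname(model$theta[["v"]])))
  for (i in seq_along(model$covariates)) {
    tm <- model$covariates[[i]]
    p[paste0("beta_", tm$param, "_", tm$cov)] <- tm$est
  }
  p["lo2_cl"] <- log(unname(model$omega2[["cl"]]))
  p["lo2_v"] <- log(unname(model$omega2[["v"]]))
  if (model$error == "combined") {
    p["ls2_prop"] <- log(unname(model$sigma2[["prop"]]))
    p["ls2_add"] <- log(unname(model$sigma2[["add"]]))
  } else {
    p["ls2"] <- log(unname(model$sigma2))
  }
  p
}

unpack_params <- function(p, template) {
  m <- template
  m$theta[["cl"]] <- exp(p[["lth_cl"]])
  m$theta[["v"]] <- exp(p[["lth_v"]])
  for (i in seq_along(m$covariates)) {
    tm <- m$covariates[[i]]
    m$covariates[[i]]$est <- p[[paste0("beta_", tm$param, "_", tm$cov)]]
  }
  m$omega2[["cl"]] <- exp(p[["lo2_cl"]])
  m$omega2[["v"]] <- exp(p[["lo2_v"]])
  if (m$error == "combined") {
    m$sigma2 <- c(prop = exp(p[["ls2_prop"]]), add = exp(p[["ls2_add"]]))
  } else {
    m$sigma2 <- exp(p[["ls2"]])
  }
  m
}

# Natural-scale parameter vector matching pack_params() ordering, plus the
# Jacobian diagonal d(natural)/d(transformed) for delta-method SEs.
natural_params <- function(model) {
  est <- c(theta_cl = unname(model$theta[["cl"]]),
           theta_v = unname(model$theta[["v"]]))
  jac <- c(est[["theta_cl"]], est[["theta_v"]])
  for (tm in model$covariates) {
    est[paste0("beta_", tm$param, "_", tm$cov)] <- tm$est
    jac <- c(jac, 1)
  }
  est["omega2_cl"] <- unname(model$omega2[["cl"]])
  est["omega2_v"] <- unname(model$omega2[["v"]])
  jac <- c(jac, est[["omega2_cl"]], est[["omega2_v"]])
  if (model$error == "combined") {
    est["sigma2_prop"] <- unname(model$sigma2[["prop"]])
    est["sigma2_add"] <- unname(model$sigma2[["add"]])
    jac <- c(jac, est[["sigma2_prop"]], est[["sigma2_add"]])
  } else {
    est["sigma2"] <- unname(model$sigma2)
    jac <- c(jac, est[["sigma2"]])
  }
  list(est = est, jac = jac)
}

err_spec <- function(model) {
  switch(model$error,
         exponential = list(code = 0L, s2a = unname(model$sigma2), s2p = 0),
         additive = list(code = 1L, s2a = unname(model$sigma2), s2p = 0),
         combined = list(code = 2L, s2a = unname(model$sigma2[["add"]]),
                         s2p = unname(model$sigma2[["prop"]])))
}

subject_tv <- function(model, subs) {
  typical_params(model, weight = subs$weight, age = subs$age,
                 egfr = subs$egfr, sex = subs$sex)
}

kernel_call <- function(split, subs, model, eta_start = NULL,
                        detail = FALSE) {
  tv <- subject_tv(model, subs)
  es <- err_spec(model)
  if (is.null(eta_start))
    eta_start <- matrix(0, nrow = length(split), ncol = 2)
  foce_kernel(unname(split), tv$cl, tv$v,
              c(unname(model$omega2[["cl"]]), unname(model$omega2[["v"]])),
              es$code, es$s2a, es$s2p, eta_start, detail)
}

# --- public surface ---------------------------------------------------------

#' FOCE-I objective function value
#'
#' Computes the conditional (FOCE-I class) approximation to
#' \eqn{-2 \log} of the marginal likelihood: per subject, the conditional
#' mode \eqn{\hat\eta} of the random effects is located by Gauss-Newton
#' iteration, and the Laplacian approximation is accumulated using the
#' exact curvature of the joint log-density at the mode (the Gauss-Newton
#' matrix is the fallback when that curvature is not positive definite).
#' With the default exponential residual-error model the likelihood is
#' that of the log-transformed concentrations, so the eta-epsilon
#' interaction is exact; for the additive/combined error forms the
#' eta-dependence of the residual variance is carried through the
#' conditional objective. Subjects whose inner optimization fails to
#' converge are reported in the `non_converged` attribute.
#'
#' @param ds a [pk_dataset()].
#' @param model a [pop_model()].
#' @return the OFV (numeric scalar) with attributes `eta` (matrix of
#'   conditional modes) and `non_converged` (subject ids).
#' @export
ofv_foce <- function(ds, model) {
  split <- dataset_split(ds)
  res <- kernel_call(split, ds$subjects, model)
  out <- res$ofv
  attr(out, "eta") <- res$eta
  attr(out, "non_converged") <- ds$subjects$id[!res$ok]
  out
}

#' Fit a population model by FOCE-I
#'
#' Minimizes the FOCE-I objective over the free parameters (log-transformed
#' typical values and variances, natural-scale covariate coefficients)
#' using a Nelder-Mead search followed by a quasi-Newton (BFGS) polish.
#' Standard errors come from the central finite-difference Hessian of the
#' OFV at the optimum (delta method back to the natural scale); a
#' non-positive-definite Hessian yields an absent covariance with a
#' warning. Empirical-Bayes estimates, shrinkage, and conditional weighted
#' residuals are computed at the final estimates.
#'
#' @param ds a [pk_dataset()] with at least 2 subjects.
#' @param init a [pop_model()] holding the model structure and initial
#'   values.
#' @param compute_se compute the finite-difference covariance (default
#'   TRUE; skip for speed inside simulation loops).
#' @param control list: `maxit_nm`, `maxit_bfgs`, `reltol`.
#' @return an object of class `pk_fit`: list with elements `model`
#'   (estimates as a [pop_model()]), `ofv`, `estimates` (natural-scale named
#'   vector), `se`, `rse` (%), `cov` (natural scale), `ebes`, `shrinkage`,
#'   `cwres`, `convergence`.
#' @export
fit_foce <- function(ds, init, compute_se = TRUE,
                     control = list()) {
  stopifnot(inherits(ds, "pk_dataset"), inherits(init, "pop_model"))
  if (nrow(ds$subjects) < 2) stop("need at least 2 subjects to fit")
  ctl <- utils::modifyList(list(maxit_nm = 1500, maxit_bfgs = 200,
                                reltol = 1e-6), control)
  split <- dataset_split(ds)
  subs <- ds$subjects
  warm <- new.env()
  warm$eta <- matrix(0, nrow = length(split), ncol = 2)

  obj <- function(p) {
    m <- try(unpack_params(p, init), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    res <- try(kernel_call(split, subs, m, eta_start = warm$eta),
               silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$ofv)) return(1e10)
    warm$eta <- res$eta
    res$ofv
  }

  p0 <- pack_params(init)
  nm <- optim(p0, obj, method = "Nelder-Mead",
              control = list(maxit = ctl$maxit_nm, reltol = ctl$reltol))
  bf <- try(optim(nm$par, obj, method = "BFGS",
                  control = list(maxit = ctl$maxit_bfgs,
                                 reltol = ctl$reltol,
                                 ndeps = rep(1e-5, length(p0)))),
            silent = TRUE)
  best <- if (!inherits(bf, "try-error") && bf$value <= nm$value) bf else nm
  p_hat <- best$par
  model_hat <- unpack_params(p_hat, init)

  nat <- natural_params(model_hat)
  cov_nat <- cov_t <- NULL
  se <- rse <- setNames(rep(NA_real_, length(nat$est)), names(nat$est))
  if (compute_se) {
    H <- fd_hessian(obj, p_hat, f0 = best$value)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) {
      cov_t <- 2 * solve(H)                  # OFV = -2 logL
      cov_nat <- diag(nat$jac) %*% cov_t %*% diag(nat$jac)
      dimnames(cov_nat) <- list(names(nat$est), names(nat$est))
      se <- setNames(sqrt(pmax(diag(cov_nat), 0)), names(nat$est))
      rse <- 100 * se / abs(nat$est)
    } else {
      warning("OFV Hessian not positive definite; covariance not reported")
    }
  }

  final <- kernel_call(split, subs, model_hat, eta_start = warm$eta,
                       detail = TRUE)
  ebes <- ebe_table(subs, model_hat, final)
  shr <- shrinkage_from_detail(model_hat, final)
  cw <- cwres_table(split, subs, model_hat, final)

  structure(list(model = model_hat, ofv = final$ofv, par = p_hat,
                 estimates = nat$est, se = se, rse = rse, cov = cov_nat,
                 cov_transformed = cov_t,
                 ebes = ebes, shrinkage = shr, cwres = cw,
                 convergence = list(outer = best$convergence == 0,
                                    inner_failed = subs$id[!final$ok]),
                 n_subjects = nrow(subs),
                 n_obs = sum(subs$n_obs), init = init),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("FOCE-I fit: %d subjects, %d observations, OFV = %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = round(x$rse, 1))
  print(tab)
  cat(sprintf("eta-shrinkage: CL %.1f%%, V %.1f%%; eps-shrinkage %.1f%%\n",
              x$shrinkage$eta["cl"], x$shrinkage$eta["v"], x$shrinkage$eps))
  invisible(x)
}

# Central finite-difference Hessian (relative step), symmetrized.
fd_hessian <- function(f, p, f0 = f(p), rel_step = 1e-4) {
  k <- length(p)
  h <- rel_step * pmax(abs(p), 1)
  H <- matrix(0, k, k)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    fp[i] <- f(p + ei); fm[i] <- f(p - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ei <- replace(numeric(k), i, h[i])
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(p + ei + ej) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] +
           f(p - ei - ej)) / (2 * h[i] * h[j])
    }
  }
  H
}

ebe_table <- function(subs, model, kres) {
  tv <- subject_tv(model, subs)
  eta <- kres$eta
  data.frame(id = subs$id, eta_cl = eta[, 1], eta_v = eta[, 2],
             cl = tv$cl * exp(eta[, 1]), v = tv$v * exp(eta[, 2]))
}

#' Empirical-Bayes estimates
#'
#' Per-subject conditional posterior modes of the random effects under a
#' given (typically fitted) model, with the implied individual parameters.
#' Subjects without quantifiable observations get the prior mode
#' \eqn{\hat\eta = 0}; inner non-convergence is flagged with an
#' `eta = 0` fallback.
#'
#' @param ds a [pk_dataset()].
#' @param model a [pop_model()].
#' @return data.frame: `id`, `eta_cl`, `eta_v`, `cl`, `v`, `converged`.
#' @export
empirical_bayes <- function(ds, model) {
  split <- dataset_split(ds)
  res <- kernel_call(split, ds$subjects, model, detail = TRUE)
  out <- ebe_table(ds$subjects, model, res)
  out$converged <- as.logical(res$ok)
  out$eta_cl[!out$converged] <- 0
  out$eta_v[!out$converged] <- 0
  out
}

shrinkage_from_detail <- function(model, kres) {
  eta <- kres$eta
  omega <- sqrt(c(cl = unname(model$omega2[["cl"]]),
                  v = unname(model$omega2[["v"]])))
  eta_shr <- setNames(rep(NA_real_, 2), c("cl", "v"))
  for (k in 1:2)
    if (omega[k] > 0) eta_shr[k] <- 100 * (1 - sd(eta[, k]) / omega[k])
  iwres <- unlist(lapply(kres$detail, function(d)
    if (!is.null(d$resid)) d$resid / sqrt(d$V) else numeric(0)))
  eps_shr <- 100 * (1 - sd(iwres))
  list(eta = eta_shr, eps = eps_shr)
}

#' Shrinkage diagnostics
#'
#' Eta-shrinkage per random effect, `100 * (1 - SD(ebe)/omega)`, and
#' epsilon-shrinkage, `100 * (1 - SD(IWRES))` with individual weighted
#' residuals taken on the scale of the residual-error model. Random effects
#' with zero variance get `NA` (undefined).
#'
#' @param ds a [pk_dataset()].
#' @param model a [pop_model()].
#' @return list with `eta` (named %, for `cl` and `v`) and `eps` (%).
#' @export
shrinkage <- function(ds, model) {
  if (nrow(ds$subjects) < 2) stop("shrinkage needs at least 2 subjects")
  res <- kernel_call(dataset_split(ds), ds$subjects, model, detail = TRUE)
  shrinkage_from_detail(model, res)
}

cwres_table <- function(split, subs, model, kres) {
  omega <- diag(c(unname(model$omega2[["cl"]]), unname(model$omega2[["v"]])),
                2, 2)
  tv <- subject_tv(model, subs)
  es <- err_spec(model)
  out <- vector("list", length(split))
  for (i in seq_along(split)) {
    s <- split[[i]]; d <- kres$detail[[i]]
    n <- length(s$obs_time)
    if (n == 0) { out[[i]] <- NULL; next }
    G <- d$G
    eta <- d$eta
    # population prediction (eta = 0)
    pred0 <- concentration(s$obs_time,
                           data.frame(time = s$dose_time, amount = s$amt,
                                      duration = s$dur),
                           list(cl = tv$cl[i], v = tv$v[i]))
    if (es$code == 0L) {
      yv <- log(s$dv)
      fhat <- yv - d$resid                 # log ipred
      mean_i <- fhat - as.vector(G %*% eta)
      cov_i <- G %*% omega %*% t(G) + diag(es$s2a, n)
      resid_pop <- yv - mean_i
    } else {
      yv <- s$dv
      fhat <- yv - d$resid
      mean_i <- fhat - as.vector(G %*% eta)
      cov_i <- G %*% omega %*% t(G) + diag(d$V, n)
      resid_pop <- yv - mean_i
    }
    cw <- tryCatch(backsolve(chol(cov_i), resid_pop, transpose = TRUE),
                   error = function(e) rep(NA_real_, n))
    out[[i]] <- data.frame(id = s$id, time = s$obs_time, dv = s$dv,
                           pred = pred0, ipred = d$ipred,
                           iwres = d$resid / sqrt(d$V), cwres = cw)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Conditional weighted residuals
#'
#' FOCE-linearized standardized residuals: the model is expanded to first
#' order about each subject's conditional mode \eqn{\hat\eta}, giving an
#' approximate marginal mean and covariance for the observation vector;
#' CWRES is the Cholesky-whitened residual, expected to have zero mean and
#' unit variance under a correct model. With the exponential error model
#' the linearization is done on log concentrations.
#'
#' @param ds a [pk_dataset()].
#' @param model a [pop_model()] (typically fitted).
#' @return data.frame: `id`, `time`, `dv`, `pred` (population prediction),
#'   `ipred` (individual prediction), `iwres`, `cwres`.
#' @export
cwres <- function(ds, model) {
  split <- dataset_split(ds)
  res <- kernel_call(split, ds$subjects, model, detail = TRUE)
  cwres_table(split, ds$subjects, model, res)
}
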