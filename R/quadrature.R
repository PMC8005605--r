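#' Marginal-likelihood OFV by adaptive Gauss-Hermite quadrature
#'
#' Reference implementation of \eqn{-2 \log} marginal likelihood for small
#' instances, used to validate the FOCE-I approximation: per subject the
#' 2-d random-effect integral is evaluated on a tensor product of
#' Gauss-Hermite nodes, centered at the conditional mode and scaled by the
#' local curvature (adaptive rule). Everything here is computed with
#' R-level arithmetic ([concentration()] and finite differences),
#' independent of the compiled FOCE kernel.
#'
#' This is an oracle for testing, not an estimation engine: cost grows as
#' `nodes^2` per subject.
#'
#' @param ds a [pk_dataset()].
#' @param model a [pop_model()] with strictly positive IIV variances.
#' @param nodes Gauss-Hermite nodes per eta dimension (default 64).
#' @return `-2 * sum(log marginal likelihood)` over subjects, same additive
#'   convention as [ofv_foce()] (for the exponential error model, the
#'   density of the log-transformed concentrations).
#' @export
ofv_agq <- function(ds, model, nodes = 64) {
  stopifnot(inherits(ds, "pk_dataset"), inherits(model, "pop_model"))
  if (any(model$omega2 <= 0))
    stop("quadrature oracle requires positive IIV variances")
  gh <- pracma::gaussHermite(nodes)
  split <- dataset_split(ds)
  tv <- subject_tv(model, ds$subjects)
  omega2 <- c(unname(model$omega2[["cl"]]), unname(model$omega2[["v"]]))

  total <- 0
  for (i in seq_along(split)) {
    s <- split[[i]]
    if (length(s$obs_time) == 0) next
    doses <- data.frame(time = s$dose_time, amount = s$amt,
                        duration = s$dur)

    nll <- function(eta) {
      cl <- tv$cl[i] * exp(eta[1])
      v <- tv$v[i] * exp(eta[2])
      if (!all(is.finite(c(cl, v))) || cl <= 0 || v <= 0) return(1e10)
      pred <- concentration(s$obs_time, doses, list(cl = cl, v = v))
      ll_obs <- switch(model$error,
        exponential = {
          if (any(pred <= 0)) return(1e10)
          sum(stats::dnorm(log(s$dv), log(pred), sqrt(model$sigma2),
                           log = TRUE))
        },
        additive = sum(stats::dnorm(s$dv, pred, sqrt(model$sigma2),
                                    log = TRUE)),
        combined = {
          v_j <- model$sigma2[["add"]] + model$sigma2[["prop"]] * pred^2
          sum(stats::dnorm(s$dv, pred, sqrt(v_j), log = TRUE))
        })
      -(ll_obs + sum(stats::dnorm(eta, 0, sqrt(omega2), log = TRUE)))
    }

    opt <- optim(c(0, 0), nll, method = "BFGS", hessian = TRUE,
                 control = list(reltol = 1e-12, maxit = 500))
    H <- opt$hessian
    eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-8)
    L <- eg$vectors %*% diag(1 / sqrt(vals))   # H^{-1} = L L'
    # integral = sqrt(2)^d |det L| sum_{jk} w_j w_k e^{z_j^2+z_k^2}
    #            exp(-nll(mode + sqrt(2) L z))
    logw <- matrix(NA_real_, nodes, nodes)
    for (j in seq_len(nodes)) {
      for (k in seq_len(nodes)) {
        z <- c(gh$x[j], gh$x[k])
        eta <- opt$par + sqrt(2) * as.vector(L %*% z)
        logw[j, k] <- log(gh$w[j]) + log(gh$w[k]) + sum(z^2) - nll(eta)
      }
    }
    mx <- max(logw)
    log_int <- mx + log(sum(exp(logw - mx))) + log(2) +
      0.5 * sum(log(1 / vals))
    total <- total - 2 * log_int
  }
  total
}
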