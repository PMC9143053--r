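# Front-end of the population estimation: dispatches to the SAEM or Laplace
# engine, then assembles empirical-Bayes estimates, the importance-sampling
# objective function, observed-information standard errors, shrinkage and the
# condition number into a `pk_fit` object.

#' Fit the population pharmacokinetic model
#'
#' Maximizes the marginal likelihood of a simultaneous IV + IM event table
#' under the two-compartment first-order-absorption model with exponential
#' between-subject variability. `method = "saem"` (default) runs the
#' stochastic approximation EM with a Metropolis-within-Gibbs E-step;
#' `method = "laplace"` optimizes the Laplace-approximate marginal deviance
#' and is deterministic. The objective function value reported for either
#' method is -2 log marginal likelihood evaluated by importance sampling at
#' the final estimates (`fit_control(compute_mofv = )`).
#'
#' @param data an event table ([generate_study()] / [read_events()]).
#' @param model a [pop_model()]; when NULL, initial values are derived from
#'   the data by [initial_estimates_from_nca()].
#' @param method `"saem"` or `"laplace"`.
#' @param seed integer seed for the stochastic steps.
#' @param control a [fit_control()] list (partial lists are merged).
#' @return An object of class `pk_fit`.
#' @export
fit_population <- function(data, model = NULL,
                           method = c("saem", "laplace"),
                           seed = 1, control = list()) {
  method <- match.arg(method)
  ctl <- utils::modifyList(fit_control(), control)
  fd <- if (is.list(data) && !is.null(data$fingerprint)) data
        else prepare_fit_data(data)
  if (fd$N < 2)
    stop("population estimation needs at least 2 subjects", call. = FALSE)
  if (is.null(model))
    model <- pop_model(initial_estimates_from_nca(data))
  eng <- if (method == "saem") saem_engine(fd, model, seed, ctl)
         else laplace_engine(fd, model, seed, ctl)
  M <- matrix(eng$mu, fd$N, 6, byrow = TRUE) + eng$O
  eb <- compute_ebe(fd, eng$mu, eng$O, eng$Omega, eng$sig,
                    start = eng$phi_last - M, hessians = TRUE)
  mofv <- if (ctl$compute_mofv)
    importance_m2ll(fd, eng$mu, eng$O, eng$Omega, eng$sig,
                    seed = seed + 1L, n_samples = ctl$is_samples, eb = eb)
  else if (method == "laplace") eng$objective else NA_real_
  pk <- make_packer(model, eng$held, eng$est)
  n_params <- pk$n_params
  status <- if (method == "laplace") {
    if (eng$status_code == 0) "converged" else "max_iter"
  } else {
    tr <- eng$trace
    late <- tr[max(1, nrow(tr) - 9):nrow(tr), seq_len(6), drop = FALSE]
    rng <- apply(late, 2, function(v) diff(range(v)) / max(abs(v[1]), 1e-12))
    if (all(rng < 0.02)) "converged" else "max_iter"
  }
  fit <- structure(list(
    method = method, model = model, seed = seed, control = ctl,
    data = fd, mu = eng$mu, Omega = eng$Omega, sig = eng$sig,
    expo = eng$expo, offsets = eng$O, est = eng$est, held = eng$held,
    theta = theta_from_phi(eng$mu),
    omega_sd = stats::setNames(sqrt(diag(eng$Omega)), .param_names),
    sigma_prop = unname(eng$sig[["prop"]]),
    sigma_add = unname(eng$sig[["add"]]),
    mofv = as.numeric(mofv), n_params = n_params,
    aic = as.numeric(mofv) + 2 * n_params,
    ebe = eb$eta, ebe_hessians = eb$hessians,
    status = status, trace = eng$trace,
    fingerprint = fd$fingerprint), class = "pk_fit")
  fit$shrinkage <- shrinkage(fit)
  if (ctl$compute_se) fit <- add_standard_errors(fit)
  fit
}

#' Construct a fit object from known parameters
#'
#' Wraps externally known (e.g. published or generative) population
#' parameters and a data set into the `pk_fit` container so the evaluation
#' tools ([vpc()], [simulate_regimen()], [residual_diagnostics()]) can be run
#' without estimation.
#'
#' @param theta typical values ([theta_fixed()]).
#' @param omega_sd named log-scale SDs (missing parameters get 0.15).
#' @param sigma_prop proportional residual SD.
#' @param data event table the object should carry.
#' @return A `pk_fit` object (without estimation by-products).
#' @export
pk_fit_manual <- function(theta, omega_sd, sigma_prop, data) {
  gen <- generative_model(theta, omega_sd, sigma_prop = sigma_prop)
  fd <- prepare_fit_data(data)
  structure(list(
    method = "manual", model = NULL, seed = NA_integer_,
    control = fit_control(), data = fd,
    mu = phi_from_theta(gen$theta), Omega = diag(gen$omega_sd^2),
    sig = c(prop = sigma_prop, add = 0), expo = c(0, 0),
    offsets = matrix(0, fd$N, 6), est = integer(0), held = integer(0),
    theta = theta_from_phi(phi_from_theta(gen$theta)),
    omega_sd = gen$omega_sd, sigma_prop = sigma_prop, sigma_add = 0,
    mofv = NA_real_, n_params = 0L, aic = NA_real_, ebe = NULL,
    status = "manual", trace = NULL,
    fingerprint = fd$fingerprint), class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("Population PK fit (", x$method, "), status: ", x$status, "\n", sep = "")
  cat(sprintf("  subjects: %d, observations: %d\n", x$data$N, x$data$n_obs))
  if (is.finite(x$mofv))
    cat(sprintf("  MOFV: %.3f  AIC: %.3f  (params: %d)\n",
                x$mofv, x$aic, x$n_params))
  print(coef_table(x), row.names = FALSE)
  invisible(x)
}

#' Tidy coefficient table of a population fit
#'
#' Typical values on the natural scale, variabilities and residual error as
#' CV%, with relative standard errors when available.
#'
#' @param fit a `pk_fit`.
#' @return A data.frame with columns `parameter`, `estimate`, `rse_pct`.
#' @export
coef_table <- function(fit) {
  est_names <- .param_names[fit$est]
  rows <- data.frame(
    parameter = c(.param_names,
                  paste0("IIV_", est_names),
                  if (fit$sig[["prop"]] > 0) "sigma_prop",
                  if (fit$sig[["add"]] > 0) "sigma_add",
                  if (any(fit$expo != 0)) c("exp_flow", "exp_volume")),
    estimate = c(unname(fit$theta["CL"]), unname(fit$theta["Vc"]),
                 unname(fit$theta["CLD"]), unname(fit$theta["VP"]),
                 unname(fit$theta["Ka"]), unname(fit$theta["F"]) * 100,
                 100 * unname(fit$omega_sd[est_names]),
                 if (fit$sig[["prop"]] > 0) 100 * fit$sig[["prop"]],
                 if (fit$sig[["add"]] > 0) fit$sig[["add"]],
                 if (any(fit$expo != 0)) fit$expo))
  rows$rse_pct <- if (!is.null(fit$rse_pct))
    fit$rse_pct[rows$parameter] else NA_real_
  rows
}

# observed Fisher information from the Laplace marginal deviance
add_standard_errors <- function(fit) {
  fd <- fit$data
  pk <- make_packer(fit$model, fit$held, fit$est)
  mu0 <- fit$mu; Omega0 <- fit$Omega; sig0 <- fit$sig; expo0 <- fit$expo
  x <- if (is.null(fit$model) || fit$model$covariate == "none")
    rep(0, fd$N) else log(fd$bw / fit$model$ref_bw)
  cache_eta <- fit$ebe
  obj <- function(p) {
    u <- pk$unpack(p, mu0, Omega0, sig0, expo0)
    O <- .cov_offsets(x, u$expo)
    as.numeric(laplace_m2ll(fd, u$mu, O, u$Omega, u$sig, start = cache_eta))
  }
  p0 <- pk$pack(mu0, Omega0, sig0, expo0)
  H <- try(fd_hessian(obj, p0, h = 5e-3), silent = TRUE)
  if (inherits(H, "try-error")) {
    warning("standard-error computation failed; RSEs unavailable")
    return(fit)
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    # the SAEM point carries Monte-Carlo noise, so the deviance Hessian can
    # be indefinite in near-flat directions; clamp and flag
    warning("information matrix is not positive definite; ",
            "standard errors use an eigenvalue-clamped approximation")
    fit$fim_indefinite <- TRUE
    ev$values <- pmax(ev$values, 1e-8 * max(ev$values))
  }
  cov <- 2 * ev$vectors %*% (t(ev$vectors) / ev$values)  # H ~ 2 * information
  if (any(!is.finite(cov)) || any(diag(cov) <= 0)) {
    warning("information matrix is singular; RSEs unavailable")
    fit$fim_singular <- TRUE
    return(fit)
  }
  se <- sqrt(diag(cov))
  est_names <- .param_names[fit$est]
  lbl <- c(.param_names[pk$mu_free], paste0("IIV_", est_names),
           if (length(pk$sig_free))
             paste0("sigma_", pk$sig_free),
           if (pk$est_expo) c("exp_flow", "exp_volume"))
  rse <- numeric(length(se))
  i_mu <- seq_along(pk$mu_free)
  rse[i_mu] <- 100 * se[i_mu]
  if (6L %in% pk$mu_free) {   # logit scale: relative error of F itself
    pos <- match(6L, pk$mu_free)
    rse[pos] <- 100 * se[pos] * (1 - fit$theta[["F"]])
  }
  rse[-i_mu] <- 100 * se[-i_mu]   # log-scale SD/sigma params, abs for expo
  if (pk$est_expo) {
    i_ex <- length(se) - 1:0
    rse[i_ex] <- ifelse(abs(fit$expo) > 1e-8,
                        100 * se[i_ex] / abs(fit$expo), NA_real_)
  }
  fit$rse_pct <- stats::setNames(rse, lbl)
  fit$cov_pack <- cov
  fit$cov_labels <- lbl
  fit$condition_number <- condition_number(fit)
  fit
}

#' Eigenvalue-ratio condition number
#'
#' Ratio of the largest to the smallest eigenvalue of the correlation matrix
#' of the fixed-effect estimates. For a fitted model this requires the
#' observed-information covariance (`fit_control(compute_se = TRUE)`); a
#' correlation matrix can also be passed directly.
#'
#' @param x a `pk_fit` with standard errors, or a correlation (or covariance)
#'   matrix.
#' @return The condition number (>= 1).
#' @export
condition_number <- function(x) UseMethod("condition_number")

#' @export
condition_number.matrix <- function(x) {
  cr <- if (all(abs(diag(x) - 1) < 1e-12)) x else stats::cov2cor(x)
  ev <- eigen(cr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("correlation matrix is not positive definite")
    return(Inf)
  }
  max(ev) / min(ev)
}

#' @export
condition_number.pk_fit <- function(x) {
  if (is.null(x$cov_pack))
    stop("fit carries no covariance matrix; refit with compute_se = TRUE",
         call. = FALSE)
  pk_mu <- grep("^(CL|Vc|CLD|VP|Ka|F)$", x$cov_labels)
  condition_number(stats::cov2cor(x$cov_pack[pk_mu, pk_mu, drop = FALSE]))
}

#' Shrinkage of the empirical-Bayes estimates and residuals
#'
#' `eta`-shrinkage per estimated variability,
#' `100 (1 - SD(EBE_j) / omega_j)`, and `epsilon`-shrinkage,
#' `100 (1 - SD(IWRES))`.
#'
#' @param fit a converged `pk_fit`.
#' @return List with `eta_pct` (named vector) and `eps_pct`.
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  if (is.null(fit$ebe)) stop("fit carries no EBEs", call. = FALSE)
  est <- fit$est
  eta_pct <- if (length(est)) {
    om <- sqrt(diag(fit$Omega))[est]
    eta_sd <- apply(fit$ebe[, est, drop = FALSE], 2, stats::sd)
    stats::setNames(100 * (1 - eta_sd / om), paste0("eta_", .param_names[est]))
  } else numeric(0)
  dg <- residual_diagnostics(fit)
  list(eta_pct = eta_pct, eps_pct = 100 * (1 - stats::sd(dg$IWRES)))
}

#' Residual diagnostic tables
#'
#' Population predictions (`PRED`, random effects at zero), individual
#' predictions (`IPRED`, at the empirical-Bayes modes), individually weighted
#' residuals (`IWRES = (y - IPRED) / sd(IPRED)`) and conditional weighted
#' residuals (`CWRES`) from a first-order linearization of the model around
#' the empirical-Bayes modes.
#'
#' @param fit a `pk_fit` with EBEs (or a [pk_fit_manual()] object, for which
#'   EBEs are computed on the fly).
#' @return A data.frame with one row per observation: `ID`, `route`, `time`,
#'   `DV`, `PRED`, `IPRED`, `IWRES`, `CWRES`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  fd <- fit$data
  if (is.null(fit$ebe)) {
    eb <- compute_ebe(fd, fit$mu, fit$offsets, fit$Omega, fit$sig)
    fit$ebe <- eb$eta
  }
  M <- matrix(fit$mu, fd$N, 6, byrow = TRUE) + fit$offsets
  pred_pop <- .pred_mats(M, fd)
  pred_ind <- .pred_mats(M + fit$ebe, fd)
  out <- list()
  for (k in seq_len(fd$N)) {
    y <- c(); tm <- c(); rt <- c(); f0 <- c(); fi <- c()
    for (r in c("iv", "im")) {
      if (is.null(fd[[r]])) next
      keep <- !is.na(fd[[r]]$Y[k, ])
      if (!any(keep)) next
      y <- c(y, fd[[r]]$Y[k, keep])
      tm <- c(tm, fd[[r]]$times[keep])
      rt <- c(rt, rep(r, sum(keep)))
      f0 <- c(f0, pred_pop[[r]][k, keep])
      fi <- c(fi, pred_ind[[r]][k, keep])
    }
    sd_i <- .resid_sd(pmax(fi, 1e-12), fit$sig)
    iwres <- (y - fi) / sd_i
    # linearized conditional residuals
    fdk <- .fd_subject(fd, k)
    eta_k <- fit$ebe[k, ]
    fvec <- function(eta) {
      pm <- .pred_mats(matrix(M[k, ] + eta, 1), fdk)
      v <- c()
      for (r in c("iv", "im")) {
        if (is.null(fdk[[r]])) next
        keep <- !is.na(fdk[[r]]$Y[1, ])
        v <- c(v, pm[[r]][1, keep])
      }
      v
    }
    J <- matrix(0, length(y), 6)
    for (j in seq_len(6)) {
      h <- 1e-4
      ej <- replace(numeric(6), j, h)
      J[, j] <- (fvec(eta_k + ej) - fvec(eta_k - ej)) / (2 * h)
    }
    cwres <- .cwres_linear(y, fi, J, eta_k, fit$Omega, sd_i)
    out[[k]] <- data.frame(ID = fd$ids[k], route = rt, time = tm, DV = y,
                           PRED = f0, IPRED = fi, IWRES = iwres,
                           CWRES = cwres)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# FOCE-style conditional weighted residuals from the linearization
# y ~ f(eta_hat) + J (eta - eta_hat) + eps around the empirical-Bayes mode:
# E[y] = f(eta_hat) - J eta_hat, Cov[y] = J Omega J' + diag(sd^2)
.cwres_linear <- function(y, f_hat, J, eta_hat, Omega, sd_i) {
  V <- J %*% Omega %*% t(J) + diag(sd_i^2, length(y))
  res <- y - (f_hat - as.numeric(J %*% eta_hat))
  drop(forwardsolve(t(chol(V)), res))
}

#' Compare two population models
#'
#' Nested models are compared by the drop in objective function against the
#' chi-squared critical value at p = 0.005 (7.879 for one extra parameter);
#' non-nested models (equal parameter counts) by the Akaike information
#' criterion `AIC = MOFV + 2 n_params`.
#'
#' @param fit_a,fit_b two `pk_fit`s of the same data set.
#' @param df_extra degrees of freedom separating the models; defaults to the
#'   difference in parameter counts (0 forces the AIC route).
#' @return List with `decision` (`"a"` or `"b"`), `nested`, `delta_mofv`,
#'   `critical`, `df` and the two AICs.
#' @export
compare_models <- function(fit_a, fit_b, df_extra = NULL) {
  stopifnot(inherits(fit_a, "pk_fit"), inherits(fit_b, "pk_fit"))
  if (!isTRUE(all.equal(fit_a$fingerprint, fit_b$fingerprint)))
    stop("fits are not based on the same data; refusing to compare",
         call. = FALSE)
  if (is.null(df_extra)) df_extra <- abs(fit_a$n_params - fit_b$n_params)
  if (df_extra > 0) {
    big <- if (fit_a$n_params >= fit_b$n_params) "a" else "b"
    small <- setdiff(c("a", "b"), big)
    fits <- list(a = fit_a, b = fit_b)
    delta <- fits[[small]]$mofv - fits[[big]]$mofv
    crit <- stats::qchisq(0.995, df_extra)
    list(decision = if (delta > crit) big else small, nested = TRUE,
         delta_mofv = delta, critical = crit, df = df_extra,
         aic_a = fit_a$mofv + 2 * fit_a$n_params,
         aic_b = fit_b$mofv + 2 * fit_b$n_params)
  } else {
    aic_a <- fit_a$mofv + 2 * fit_a$n_params
    aic_b <- fit_b$mofv + 2 * fit_b$n_params
    list(decision = if (aic_a <= aic_b) "a" else "b", nested = FALSE,
         delta_mofv = NA_real_, critical = NA_real_, df = 0,
         aic_a = aic_a, aic_b = aic_b)
  }
}
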