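# Stochastic approximation EM for the population model. The E-step is a
# Metropolis-within-Gibbs sampler over the subject-level transformed
# parameters phi_i, vectorized across subjects; because the population means
# enter phi linearly, every M-step update (means, covariate slopes, omega,
# residual variance) is closed form in the smoothed sufficient statistics.

#' Control settings for the population fit
#'
#' @param n_burn exploration iterations with unit step size (step 1 phase);
#'   during this phase the variance updates are annealed (never shrunk by more
#'   than 5% per iteration) to avoid premature collapse.
#' @param n_iter smoothing iterations with step size `1/k^step_power`.
#' @param step_power exponent of the decreasing step-size schedule.
#' @param rw_reps repetitions of the joint random-walk kernel per iteration.
#' @param sigma_min lower floor of residual SD parameters.
#' @param omega_min_sd lower floor of estimated variability SDs.
#' @param compute_se compute the observed-information standard errors
#'   (finite differences of the Laplace marginal deviance; the slow part).
#' @param compute_mofv evaluate the objective function (-2 marginal
#'   log-likelihood) by importance sampling at the final estimates.
#' @param is_samples importance-sampling draws per subject (documented source
#'   of the sub-unit jitter in repeated MOFV evaluations).
#' @param laplace_maxit outer iteration cap of the Laplace optimizer.
#' @return A list of control settings.
#' @export
fit_control <- function(n_burn = 150, n_iter = 150, step_power = 0.7,
                        rw_reps = 2, sigma_min = 1e-3, omega_min_sd = 1e-3,
                        compute_se = FALSE, compute_mofv = TRUE,
                        is_samples = 1000, laplace_maxit = 200) {
  as.list(environment())
}

# multivariate normal prior rows: phi (N x 6), centre M (N x 6)
.lprior_rows <- function(phi, M, U_inv, logdet) {
  Z <- (phi - M) %*% U_inv
  -0.5 * rowSums(Z^2) - 0.5 * logdet - 3 * log(2 * pi)
}

.sigma_pack <- function(model) {
  s <- model$sigma_init
  switch(model$error,
         proportional = c(prop = s[["prop"]], add = 0),
         additive = c(prop = 0, add = s[["add"]]),
         combined = c(prop = s[["prop"]], add = s[["add"]]))
}

# which phi components cannot be informed by the available routes
.held_components <- function(fd) {
  held <- integer(0)
  if (is.null(fd$im)) held <- c(held, 5L, 6L)   # Ka and F need IM data
  else if (is.null(fd$iv)) held <- c(held, 6L)  # F needs both routes
  held
}

saem_engine <- function(fd, model, seed, control) {
  ctl <- utils::modifyList(fit_control(), control)
  N <- fd$N
  x <- if (model$covariate == "none" || all(is.na(fd$bw))) rep(0, N)
       else log(fd$bw / model$ref_bw)
  expo <- switch(model$covariate,
                 none = c(0, 0),
                 allometric_fixed = c(0.75, 1),
                 allometric_estimated = c(0.75, 1))
  est_expo <- model$covariate == "allometric_estimated"
  mu <- phi_from_theta(model$theta_init)
  held <- .held_components(fd)
  if (length(held))
    warning("only one route in the data; holding ",
            paste(.param_names[held], collapse = ", "), " at initial values")
  est <- setdiff(model$est_idx, held)
  fix_idx <- setdiff(seq_len(6), est)
  omega2 <- model$omega_sd_init^2
  sig <- .sigma_pack(model)
  O <- .cov_offsets(x, expo)
  xc <- x - mean(x)
  sxx <- sum(xc^2)

  with_seed(seed, {
    phi <- matrix(mu, N, 6, byrow = TRUE) + O
    Omega <- diag(omega2)
    rho_B <- 0.5
    rho_C <- rep(1, 6)
    Sphi <- NULL
    n_tot <- ctl$n_burn + ctl$n_iter
    trace <- matrix(NA_real_, n_tot, 6 + 6 + 2 + 2,
                    dimnames = list(NULL, c(.param_names,
                                            paste0("om2_", .param_names),
                                            "sig_prop", "sig_add",
                                            "exp_flow", "exp_vol")))
    for (it in seq_len(n_tot)) {
      gamma <- if (it <= ctl$n_burn) 1 else (it - ctl$n_burn)^(-ctl$step_power)
      U <- chol(Omega)
      U_inv <- backsolve(U, diag(6))
      logdet <- 2 * sum(log(diag(U)))
      M <- matrix(mu, N, 6, byrow = TRUE) + O
      ll_cur <- .ll_rows(phi, fd, sig)

      # kernel A: independent draws from the current population distribution
      prop <- M + matrix(stats::rnorm(N * 6), N, 6) %*% U
      llp <- .ll_rows(prop, fd, sig)
      acc <- log(stats::runif(N)) < llp - ll_cur
      phi[acc, ] <- prop[acc, ]
      ll_cur[acc] <- llp[acc]
      lp_cur <- .lprior_rows(phi, M, U_inv, logdet)

      # kernel B: joint random walk, adapted towards ~40% acceptance
      sd_w <- sqrt(diag(Omega))
      for (r in seq_len(ctl$rw_reps)) {
        prop <- phi + matrix(stats::rnorm(N * 6), N, 6) *
          matrix(rho_B * sd_w, N, 6, byrow = TRUE)
        llp <- .ll_rows(prop, fd, sig)
        lpp <- .lprior_rows(prop, M, U_inv, logdet)
        acc <- log(stats::runif(N)) < (llp + lpp) - (ll_cur + lp_cur)
        phi[acc, ] <- prop[acc, ]
        ll_cur[acc] <- llp[acc]
        lp_cur[acc] <- lpp[acc]
        rho_B <- min(max(rho_B * exp(0.4 * (mean(acc) - 0.4)), 1e-3), 10)
      }

      # kernel C: one componentwise pass
      for (j in seq_len(6)) {
        prop <- phi
        prop[, j] <- phi[, j] + stats::rnorm(N, 0, rho_C[j] * sd_w[j])
        llp <- .ll_rows(prop, fd, sig)
        lpp <- .lprior_rows(prop, M, U_inv, logdet)
        acc <- log(stats::runif(N)) < (llp + lpp) - (ll_cur + lp_cur)
        phi[acc, ] <- prop[acc, ]
        ll_cur[acc] <- llp[acc]
        lp_cur[acc] <- lpp[acc]
        rho_C[j] <- min(max(rho_C[j] * exp(0.4 * (mean(acc) - 0.4)), 1e-3), 10)
      }

      # sufficient statistics at the current draws
      preds <- .pred_mats(phi, fd)
      eps_new <- 0
      r2_new <- list(); fm_new <- list()
      for (rt in names(preds)) {
        Y <- fd[[rt]]$Y
        Fm <- pmax(preds[[rt]], 1e-12)
        if (model$error == "proportional")
          eps_new <- eps_new + sum(((Y - Fm) / Fm)^2, na.rm = TRUE)
        else if (model$error == "additive")
          eps_new <- eps_new + sum((Y - Fm)^2, na.rm = TRUE)
        else {
          r2_new[[rt]] <- (Y - Fm)^2
          fm_new[[rt]] <- Fm
        }
      }
      if (is.null(Sphi)) {
        Sphi <- phi
        Sxx <- crossprod(phi)
        Seps <- eps_new
        Sr2 <- r2_new; Sfm <- fm_new
      } else {
        Sphi <- Sphi + gamma * (phi - Sphi)
        Sxx <- Sxx + gamma * (crossprod(phi) - Sxx)
        Seps <- Seps + gamma * (eps_new - Seps)
        if (model$error == "combined")
          for (rt in names(r2_new)) {
            Sr2[[rt]] <- Sr2[[rt]] + gamma * (r2_new[[rt]] - Sr2[[rt]])
            Sfm[[rt]] <- Sfm[[rt]] + gamma * (fm_new[[rt]] - Sfm[[rt]])
          }
      }

      # M-step: means and covariate slopes
      m1 <- colMeans(Sphi)
      if (est_expo && sxx > 0) {
        ctr <- sweep(Sphi, 2, m1)
        expo[1] <- sum(xc * rowSums(ctr[, .flow_idx, drop = FALSE])) /
          (length(.flow_idx) * sxx)
        expo[2] <- sum(xc * rowSums(ctr[, .vol_idx, drop = FALSE])) /
          (length(.vol_idx) * sxx)
      }
      O <- .cov_offsets(x, expo)
      mu_new <- m1 - colMeans(O)
      mu_new[6] <- min(mu_new[6], stats::qlogis(0.999))  # keep F off 1
      mu_new[held] <- mu[held]
      mu <- mu_new

      # M-step: omega (closed form in the smoothed second moments)
      M <- matrix(mu, N, 6, byrow = TRUE) + O
      V <- (Sxx - crossprod(M, Sphi) - crossprod(Sphi, M) + crossprod(M)) / N
      V <- (V + t(V)) / 2
      new_diag <- pmax(diag(V), ctl$omega_min_sd^2)
      if (it <= ctl$n_burn) new_diag <- pmax(new_diag, 0.95 * diag(Omega))
      Omega_new <- diag(ifelse(seq_len(6) %in% est, new_diag, omega2))
      if (model$full_block && length(est) > 1) {
        blk <- V[est, est]
        diag(blk) <- new_diag[est]
        ev <- eigen(blk, symmetric = TRUE)
        ev$values <- pmax(ev$values, 1e-8)
        Omega_new[est, est] <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
      }
      Omega <- Omega_new

      # M-step: residual variance
      if (!model$sigma_fixed) {
        if (model$error == "proportional") {
          s2 <- max(Seps / fd$n_obs, ctl$sigma_min^2)
          if (it <= ctl$n_burn) s2 <- max(s2, (0.95 * sig[["prop"]])^2)
          sig[["prop"]] <- sqrt(s2)
        } else if (model$error == "additive") {
          s2 <- max(Seps / fd$n_obs, ctl$sigma_min^2)
          if (it <= ctl$n_burn) s2 <- max(s2, (0.95 * sig[["add"]])^2)
          sig[["add"]] <- sqrt(s2)
        } else {
          nll <- function(p) {
            a <- exp(p[1]); b <- exp(p[2]); tot <- 0
            for (rt in names(Sr2)) {
              v <- a^2 + (b * Sfm[[rt]])^2
              tot <- tot + sum(log(v) + Sr2[[rt]] / v, na.rm = TRUE)
            }
            tot
          }
          op <- stats::nlminb(log(pmax(sig[c("add", "prop")], ctl$sigma_min)),
                              nll)
          sig[["add"]] <- max(exp(op$par[1]), ctl$sigma_min)
          sig[["prop"]] <- max(exp(op$par[2]), ctl$sigma_min)
        }
      }
      trace[it, ] <- c(theta_from_phi(mu), diag(Omega), sig, expo)
    }
    list(mu = mu, Omega = Omega, sig = sig, expo = expo, x = x, O = O,
         est = est, held = held, phi_last = phi, trace = trace,
         n_iter_run = n_tot)
  })
}
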