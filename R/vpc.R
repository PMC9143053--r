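# Visual predictive check: percentile bands of replicate data sets simulated
# at the final estimates, compared with the observed percentiles.

# upper-triangular-like square root tolerant of singular (zero-variance)
# covariance matrices
.cov_sqrt <- function(S) {
  if (all(S == 0)) return(matrix(0, nrow(S), ncol(S)))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

# simulate replicate observation matrices under the fit's estimates, on the
# fit's own design (same subjects, doses, sampling times, missingness)
.simulate_replicates <- function(fit, n_replicates, seed) {
  fd <- fit$data
  N <- fd$N
  NR <- N * n_replicates
  with_seed(seed, {
    U <- .cov_sqrt(fit$Omega)
    eta <- matrix(stats::rnorm(NR * 6), NR, 6) %*% U
    Mbig <- matrix(fit$mu, NR, 6, byrow = TRUE) +
      fit$offsets[rep(seq_len(N), n_replicates), , drop = FALSE]
    phi <- Mbig + eta
    out <- list()
    for (r in c("iv", "im")) {
      if (is.null(fd[[r]])) next
      dose <- rep(fd[[r]]$dose, n_replicates)
      m <- .micro_vec(exp(phi[, 1]), exp(phi[, 2]), exp(phi[, 3]),
                      exp(phi[, 4]))
      Fm <- if (r == "iv") .conc_iv_mat(m, dose, fd[[r]]$times)
            else .conc_im_mat(m, exp(phi[, 5]), stats::plogis(phi[, 6]),
                              dose, fd[[r]]$times)
      sd_m <- .resid_sd(pmax(Fm, 1e-12), fit$sig)
      Ysim <- Fm + matrix(stats::rnorm(length(Fm)), nrow(Fm)) * sd_m
      mask <- is.na(fd[[r]]$Y[rep(seq_len(N), n_replicates), , drop = FALSE])
      Ysim[mask] <- NA_real_
      out[[r]] <- Ysim
    }
    out
  })
}

#' Visual predictive check
#'
#' Simulates `n_replicates` data sets from the fitted model on the original
#' design (same subjects, doses, sampling times), computes the observed and
#' simulated percentiles per route and nominal sampling time, and the
#' confidence interval of each simulated percentile across replicates. Time
#' bins are the design's nominal sampling times; with a sparse fixed schedule
#' no binning algorithm is needed.
#'
#' @param fit a `pk_fit` (estimated or [pk_fit_manual()]).
#' @param n_replicates number of simulated replicates (default 1000; fewer
#'   than 100 triggers a warning about unstable CIs).
#' @param seed integer seed; results are reproducible given
#'   (`seed`, `n_replicates`).
#' @param pi_level width of the prediction interval summarized by the outer
#'   percentiles (default 0.95: 2.5th/97.5th).
#' @param ci_level confidence level for the simulated percentile bands
#'   (default 0.975).
#' @return A data.frame of class `vpc_summary`: per route and time the
#'   observed percentiles (`obs_lo`, `obs_md`, `obs_hi`), the simulated CI
#'   bounds for each (`sim_*_lwr`, `sim_*_upr`) and `n_obs`.
#' @export
vpc <- function(fit, n_replicates = 1000, seed = 1, pi_level = 0.95,
                ci_level = 0.975) {
  stopifnot(inherits(fit, "pk_fit"))
  if (n_replicates < 100)
    warning("fewer than 100 replicates gives unstable percentile CIs")
  probs <- c((1 - pi_level) / 2, 0.5, 1 - (1 - pi_level) / 2)
  ci <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  sims <- .simulate_replicates(fit, n_replicates, seed)
  fd <- fit$data
  N <- fd$N
  out <- list()
  for (r in names(sims)) {
    Yobs <- fd[[r]]$Y
    tms <- fd[[r]]$times
    for (j in seq_along(tms)) {
      yo <- Yobs[, j]
      yo <- yo[!is.na(yo)]
      if (!length(yo)) next
      obs_q <- stats::quantile(yo, probs, names = FALSE)
      S <- matrix(sims[[r]][, j], N, n_replicates)
      sim_q <- apply(S, 2, stats::quantile, probs = probs, na.rm = TRUE)
      band <- apply(sim_q, 1, stats::quantile, probs = ci, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        route = r, time = tms[j], n_obs = length(yo),
        obs_lo = obs_q[1], obs_md = obs_q[2], obs_hi = obs_q[3],
        sim_lo_lwr = band[1, 1], sim_lo_upr = band[2, 1],
        sim_md_lwr = band[1, 2], sim_md_upr = band[2, 2],
        sim_hi_lwr = band[1, 3], sim_hi_upr = band[2, 3])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_replicates") <- n_replicates
  attr(res, "pi_level") <- pi_level
  attr(res, "ci_level") <- ci_level
  class(res) <- c("vpc_summary", "data.frame")
  res
}

#' Fraction of observed percentiles inside their simulated bands
#'
#' Convenience metric for VPC calibration checks: the share of
#' (route, time, percentile) points whose observed value falls inside the
#' simulated confidence band.
#'
#' @param v a [vpc()] summary.
#' @return A fraction in `[0, 1]`.
#' @export
vpc_coverage <- function(v) {
  inside <- c(v$obs_lo >= v$sim_lo_lwr & v$obs_lo <= v$sim_lo_upr,
              v$obs_md >= v$sim_md_lwr & v$obs_md <= v$sim_md_upr,
              v$obs_hi >= v$sim_hi_lwr & v$obs_hi <= v$sim_hi_upr)
  mean(inside)
}
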