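# Population estimation: conditional likelihood, noiseless identifiability,
# model comparison, allometry, shrinkage, condition number, residuals and
# engine-level invariants. The full 200-subject recovery experiment lives in
# test-acceptance.R.

small_study <- function(n = 12, sigma = 0.15, seed = 31) {
  gen <- generative_model(sigma_prop = sigma)
  generate_study(study_design(n_subjects = n), gen, seed = seed)
}

test_that("subject_loglik matches direct normal-density evaluation", {
  th <- ref_theta()
  ev <- generate_study(study_design(n_subjects = 1),
                       generative_model(omega_sd = c(), fixed_omega_sd = 0,
                                        sigma_prop = 0), seed = 2)
  sub <- ev[ev$ID == 1, ]
  # zero-residual case: sum of -log(sigma f sqrt(2 pi)) over observations
  obs <- sub[sub$EVID == 0 & sub$BLANK == 0, ]
  s <- 0.2
  expect_equal(subject_loglik(sub, th, rep(0, 6), s),
               sum(-log(s * obs$DV * sqrt(2 * pi))), tolerance = 1e-10)

  # single observation, hand-computed
  one <- sub[sub$ROUTE == 1 & (sub$EVID == 1 | sub$TIME == 24), ]
  one <- one[one$BLANK == 0, ]
  dose <- one$AMT[one$EVID == 1]
  f24 <- conc_iv_bolus(th, dose, 24)
  y24 <- one$DV[one$EVID == 0]
  expect_equal(subject_loglik(one, th, rep(0, 6), s),
               stats::dnorm(y24, f24, s * f24, log = TRUE), tolerance = 1e-10)

  # non-zero eta on a noisy subject: brute-force density oracle
  ev2 <- generate_study(study_design(n_subjects = 1),
                        generative_model(sigma_prop = 0.2), seed = 5)
  sub2 <- ev2[ev2$ID == 1, ]
  eta <- c(0.2, -0.1, 0.05, 0, 0.3, -0.05)
  th_i <- as.list(unlist(th) * exp(eta))
  ll <- 0
  for (rt in 1:2) {
    blk <- sub2[sub2$ROUTE == rt, ]
    d <- blk$AMT[blk$EVID == 1]
    o <- blk[blk$EVID == 0 & blk$BLANK == 0, ]
    f <- if (rt == 1) conc_iv_bolus(as_theta_list(th_i), d, o$TIME)
         else conc_first_order_abs(as_theta_list(th_i), d, o$TIME)
    ll <- ll + sum(stats::dnorm(o$DV, f, 0.2 * f, log = TRUE))
  }
  expect_equal(subject_loglik(sub2, th, eta, 0.2), ll, tolerance = 1e-8)
})

test_that("noiseless rich data identify the generative parameters", {
  # omega = 0, sigma = 0 in generation; estimation floors sigma and omega
  gen <- generative_model(omega_sd = c(), fixed_omega_sd = 0, sigma_prop = 0)
  dense <- c(1 / 120, 0.1, 0.25, 0.5, 1, 2, 4, 6, 8, 16, 24, 48, 96)
  ev <- generate_study(study_design(n_subjects = 3, iv_times = dense,
                                    im_times = dense), gen, seed = 13)
  # deterministic limit: no estimated variability, residual SD fixed small
  md <- pop_model(initial_estimates_from_nca(ev),
                  estimated_iiv = character(0), fixed_omega_sd = 0.02,
                  sigma_init = c(prop = 0.01), sigma_fixed = TRUE)
  fit <- fit_population(ev, md, method = "laplace", seed = 1,
                        control = fit_control(compute_mofv = FALSE))
  tv <- unlist(ref_theta())
  expect_equal(unname(fit$theta[c("CL", "Vc", "Ka", "F")]),
               unname(tv[c("CL", "Vc", "Ka", "F")]), tolerance = 0.005)
})

test_that("SAEM refits of the same data agree within one MOFV unit", {
  ev <- small_study(n = 20)
  f1 <- fit_population(ev, seed = 100)
  f2 <- fit_population(ev, seed = 200)
  expect_lt(abs(f1$mofv - f2$mofv), 1)
  # point estimates agree within the chain's Monte-Carlo noise
  expect_equal(unname(f1$theta["CL"]), unname(f2$theta["CL"]),
               tolerance = 0.06)
})

test_that("fixed omega entries survive fitting bit-identically", {
  ev <- small_study(n = 8)
  fit <- fit_population(ev, seed = 4,
                        control = fit_control(n_burn = 40, n_iter = 40,
                                              compute_mofv = FALSE))
  expect_identical(unname(fit$omega_sd[c("CLD", "VP", "F")]),
                   rep(0.15, 3))
})

test_that("Laplace marginal deviance is invariant to subject order", {
  ev <- small_study(n = 6)
  perm <- ev[order(match(ev$ID, c(4, 2, 6, 1, 5, 3)),
                   ev$OCC, ev$EVID, ev$TIME), ]
  fd1 <- swinepk:::prepare_fit_data(ev)
  fd2 <- swinepk:::prepare_fit_data(perm)
  ref <- carprofen_reference()
  mu <- swinepk:::phi_from_theta(ref$theta)
  Om <- diag(c(0.33, 0.33, 0.15, 0.15, 0.95, 0.15)^2)
  sig <- c(prop = 0.24, add = 0)
  m1 <- swinepk:::laplace_m2ll(fd1, mu, matrix(0, 6, 6), Om, sig)
  m2 <- swinepk:::laplace_m2ll(fd2, mu, matrix(0, 6, 6), Om, sig)
  expect_lt(abs(as.numeric(m1) - as.numeric(m2)), 1e-6)
})

test_that("compare_models applies the chi-squared and AIC rules", {
  ev <- small_study(n = 6)
  fit <- fit_population(ev, seed = 9,
                        control = fit_control(n_burn = 30, n_iter = 30,
                                              compute_mofv = FALSE))
  fa <- fit; fb <- fit
  fa$mofv <- 1000; fa$n_params <- 10
  fb$mofv <- 1007.880; fb$n_params <- 9
  out <- compare_models(fa, fb)
  expect_true(out$nested)
  expect_equal(out$df, 1)
  expect_equal(out$critical, 7.879, tolerance = 1e-4)
  expect_equal(out$decision, "a")          # 7.880 > 7.879: keep larger model
  fb$mofv <- 1000
  expect_equal(compare_models(fa, fb)$decision, "b")  # retain simpler
  # two extra parameters: critical value is the chi-squared 99.5% quantile
  fb$n_params <- 8
  expect_equal(compare_models(fa, fb)$critical, 10.5966347, tolerance = 1e-6)
  # non-nested: lower AIC wins
  fb$n_params <- 10; fb$mofv <- 999
  expect_equal(compare_models(fa, fb)$decision, "b")
  # different data: refuse
  fc <- fit_population(small_study(n = 6, seed = 77), seed = 9,
                       control = fit_control(n_burn = 20, n_iter = 20,
                                             compute_mofv = FALSE))
  expect_error(compare_models(fa, fc), "same data")
})

test_that("apply_allometry scales flows and volumes", {
  th <- ref_theta()
  expect_equal(unlist(apply_allometry(th, 70)), unlist(th), tolerance = 1e-12)
  sc <- apply_allometry(th, 35)
  expect_equal(sc$CL, th$CL * 0.5^0.75)
  expect_equal(sc$CLD, th$CLD * 0.5^0.75)
  expect_equal(sc$Vc, th$Vc * 0.5)
  expect_equal(sc$VP, th$VP * 0.5)
  expect_equal(sc$Ka, th$Ka)
  expect_equal(sc$F, th$F)
})

test_that("allometric exponents are recovered from covariate-driven data", {
  # generate with true allometric scaling over a wide bodyweight range
  set.seed(88)
  n <- 100
  ref <- carprofen_reference()
  rows <- lapply(seq_len(n), function(i) {
    bw <- stats::runif(1, 10, 80)
    th_b <- apply_allometry(ref$theta, bw)
    eta <- stats::rnorm(6, 0, c(0.3, 0.3, 0.15, 0.15, 0.5, 0.15))
    th_i <- swinepk:::subject_theta(th_b, eta)
    dose <- 4 * bw
    build <- function(route, times) {
      f <- if (route == 1) conc_iv_bolus(as_theta_list(th_i), dose, times)
           else conc_first_order_abs(as_theta_list(th_i), dose, times)
      y <- f * (1 + stats::rnorm(length(f), 0, 0.15))
      y <- pmax(y, 1e-6)
      data.frame(ID = i, OCC = route, TIME = c(0, times),
                 AMT = c(dose, rep(0, length(times))),
                 DV = c(NA, y), EVID = c(1L, rep(0L, length(times))),
                 ROUTE = route, BW = bw, BLANK = 0L)
    }
    tms <- c(1 / 120, 0.25, 0.5, 1, 2, 4, 8, 24, 48)
    rbind(build(1, tms), build(2, tms))
  })
  ev <- do.call(rbind, rows)
  md <- pop_model(ref$theta, covariate = "allometric_estimated",
                  sigma_init = c(prop = 0.15))
  fit <- fit_population(ev, md, seed = 6,
                        control = fit_control(n_burn = 80, n_iter = 80,
                                              compute_mofv = FALSE))
  expect_lt(abs(fit$expo[1] - 0.75), 0.15)
  expect_lt(abs(fit$expo[2] - 1.0), 0.15)
})

test_that("shrinkage behaves at its analytic limits", {
  ev <- small_study(n = 10)
  fit <- fit_population(ev, seed = 15,
                        control = fit_control(n_burn = 40, n_iter = 40,
                                              compute_mofv = FALSE))
  sh <- shrinkage(fit)
  expect_named(sh$eta_pct, c("eta_CL", "eta_Vc", "eta_Ka"))
  expect_true(all(sh$eta_pct <= 100))
  # all-zero EBEs collapse to 100% shrinkage
  fit0 <- fit
  fit0$ebe <- matrix(0, fit$data$N, 6)
  expect_equal(unname(shrinkage(fit0)$eta_pct), rep(100, 3))
  # EBEs drawn exactly from the population distribution: shrinkage near zero
  fit1 <- fit
  set.seed(1)
  fit1$ebe <- matrix(stats::rnorm(4000 * 6), 4000, 6) %*%
    diag(fit$omega_sd)
  fit1$data$N <- 4000   # only ebe rows are used for the eta part
  eta_only <- 100 * (1 - apply(fit1$ebe[, fit$est], 2, stats::sd) /
                       fit$omega_sd[fit$est])
  expect_true(all(abs(eta_only) < 5))
})

test_that("rich sampling keeps eta-shrinkage low", {
  dense <- c(1 / 120, 0.1, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48,
             72, 96)
  ev <- generate_study(study_design(n_subjects = 25, iv_times = dense,
                                    im_times = dense),
                       generative_model(sigma_prop = 0.1), seed = 3)
  fit <- fit_population(ev, seed = 8,
                        control = fit_control(n_burn = 60, n_iter = 60,
                                              compute_mofv = FALSE))
  sh <- shrinkage(fit)
  expect_lt(max(sh$eta_pct[c("eta_CL", "eta_Vc")]), 20)
})

test_that("condition_number on correlation matrices and fits", {
  expect_equal(condition_number(diag(3)), 1)
  expect_equal(condition_number(matrix(c(1, 0.6, 0.6, 1), 2)), 4,
               tolerance = 1e-12)
  ev <- small_study(n = 12)
  ctl <- fit_control(n_burn = 50, n_iter = 50, compute_mofv = FALSE,
                     compute_se = TRUE)
  f1 <- fit_population(ev, seed = 21, control = ctl)
  expect_true(is.finite(f1$condition_number) && f1$condition_number > 1)
  expect_true(all(is.finite(f1$rse_pct)))
  f2 <- fit_population(ev, seed = 22, control = ctl)
  expect_lt(abs(log(f1$condition_number / f2$condition_number)), log(2))
})

test_that("residual diagnostics: identities, calibration and CWRES algebra", {
  # y == IPRED implies IWRES == 0 (noise-free data, EBE fits exactly;
  # variability only on log-scale parameters so every subject is reachable)
  gen0 <- generative_model(fixed_omega_sd = 0, sigma_prop = 0)
  ev0 <- generate_study(study_design(n_subjects = 3), gen0, seed = 44)
  man <- pk_fit_manual(carprofen_reference()$theta,
                       carprofen_reference()$omega_sd, 0.01, ev0)
  dg0 <- residual_diagnostics(man)
  expect_lt(max(abs(dg0$IWRES)), 0.1)
  # IWRES is exactly (y - IPRED) / (sigma IPRED)
  expect_equal(dg0$IWRES, (dg0$DV - dg0$IPRED) / (0.01 * dg0$IPRED),
               tolerance = 1e-10)

  # at the generative parameters IWRES is standard-normal-calibrated
  ev1 <- generate_study(study_design(n_subjects = 60), generative_model(),
                        seed = 45)
  man1 <- pk_fit_manual(carprofen_reference()$theta,
                        carprofen_reference()$omega_sd,
                        carprofen_reference()$sigma_prop, ev1)
  dg1 <- residual_diagnostics(man1)
  expect_gt(nrow(dg1), 1000)
  expect_lt(abs(mean(dg1$IWRES)), 0.1)
  expect_gt(stats::sd(dg1$IWRES), 0.85)
  expect_lt(stats::sd(dg1$IWRES), 1.15)

  # one-observation linear toy: CWRES equals the analytic standardized
  # residual (y - a) / sqrt(b^2 omega^2 + sigma^2)
  a <- 5; b <- 2; om <- 0.4; sg <- 0.3; y <- 5.9; eta_hat <- 0.15
  Om <- diag(c(om^2, rep(1e-10, 5)))
  J <- matrix(c(b, 0, 0, 0, 0, 0), 1)
  got <- swinepk:::.cwres_linear(y, a + b * eta_hat, J,
                                 c(eta_hat, rep(0, 5)), Om, sg)
  expect_equal(got, (y - a) / sqrt(b^2 * om^2 + sg^2), tolerance = 1e-10)
})

test_that("adding an unnecessary error parameter does not raise the MOFV", {
  ev <- small_study(n = 14)
  ctl <- fit_control(n_burn = 60, n_iter = 60)
  f_prop <- fit_population(ev, pop_model(initial_estimates_from_nca(ev)),
                           seed = 3, control = ctl)
  f_comb <- fit_population(ev, pop_model(initial_estimates_from_nca(ev),
                                         error = "combined"),
                           seed = 3, control = ctl)
  # within Monte-Carlo error of the importance-sampling objective
  expect_lt(f_comb$mofv, f_prop$mofv + 2)
})

test_that("one-route data hold unidentifiable parameters with a warning", {
  ev <- small_study(n = 6)
  iv_only <- ev[ev$ROUTE == 1, ]
  expect_warning(
    fit_population(iv_only, pop_model(ref_theta()), seed = 2,
                   control = fit_control(n_burn = 15, n_iter = 15,
                                         compute_mofv = FALSE)),
    "holding")
})
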