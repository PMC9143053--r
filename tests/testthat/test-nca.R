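# Non-compartmental analysis: terminal-slope regression, trapezoidal areas,
# extrapolation, moments/volumes, bioavailability and the study summary.

test_that("fit_lambda_z is exact on a mono-exponential profile", {
  tms <- c(0, 2, 6, 12, 24, 48)
  lz <- fit_lambda_z(tms, 10 * exp(-0.02 * tms))
  expect_equal(lz$status, "ok")
  expect_equal(lz$lambda_z, 0.02, tolerance = 1e-12)
  expect_equal(lz$r2_adj, 1, tolerance = 1e-12)
})

test_that("fit_lambda_z approaches beta on a late-sampled biexponential", {
  th <- ref_theta()
  m <- macro_to_micro(th)
  tms <- c(8, 24, 48, 72)
  lz <- fit_lambda_z(tms, conc_iv_bolus(th, 126, tms))
  expect_equal(lz$lambda_z, m$beta, tolerance = 0.05)
})

test_that("fit_lambda_z flags unusable profiles", {
  tms <- c(1, 2, 4, 8)
  expect_equal(fit_lambda_z(tms, c(1, 2, 3, 4))$status, "insufficient_points")
  expect_equal(fit_lambda_z(tms, c(5, 1, 2, 3))$status, "nonpositive_slope")
  expect_equal(fit_lambda_z(c(1, 2, 4), c(3, 2, 1))$status,
               "insufficient_points")   # nothing after Cmax but min_points
})

test_that("half_life", {
  expect_equal(round(half_life(0.471), 2), 1.47)
  expect_identical(half_life(log(2)), 1)
  m <- macro_to_micro(ref_theta())
  expect_equal(half_life(m$beta), log(2) / oracle_disposition_rates(ref_theta())[2],
               tolerance = 1e-10)
  expect_error(half_life(0), "positive")
})

test_that("auc_linlog interval rules", {
  # constant profile: linear rule by the non-decreasing convention
  expect_equal(auc_linlog(c(0, 10), c(5, 5)), 50)
  # log rule is exact for an exponential segment
  expect_equal(auc_linlog(c(0, 10), 10 * exp(-0.1 * c(0, 10))),
               10 * (1 - exp(-1)) / 0.1, tolerance = 1e-12)
  # dense noise-free profile integrates to dose/CL within 0.5%
  th <- ref_theta()
  tms <- seq(0, 2000, by = 0.01)
  cc <- conc_iv_bolus(th, 126, tms)
  lz <- fit_lambda_z(tms[tms >= 1500], cc[tms >= 1500])
  auc_inf <- auc_linlog(tms, cc) + lz$c_last_pred / lz$lambda_z
  expect_equal(auc_inf, 126 / th$CL, tolerance = 0.005)
})

test_that("auc_extrapolate handles boundaries and the half-life tail", {
  expect_equal(auc_extrapolate(100, 0, 0.1),
               list(auc_inf = 100, extrap_pct = 0, valid = TRUE))
  expect_warning(out <- auc_extrapolate(0, 5, 0.1), "invalid")
  expect_false(out$valid)
  # mono-exponential truncated at one half-life: half the area remains
  k <- 0.07; c0 <- 12; t_half <- log(2) / k
  tms <- seq(0, t_half, length.out = 2000)
  auc_t <- auc_linlog(tms, c0 * exp(-k * tms))
  out <- auc_extrapolate(auc_t, c0 * exp(-k * t_half), k)
  expect_equal(out$extrap_pct, 50, tolerance = 1e-6)
})

test_that("moments and volumes: one-compartment closed forms", {
  th1 <- theta_fixed(CL = 0.4, Vc = 8, CLD = 0, VP = 1, Ka = 0.5, F = 0.9)
  k10 <- 0.4 / 8
  tms <- seq(0.01, 12 / k10, by = 0.05)
  res <- nca_profile(tms, conc_iv_bolus(th1, 100, tms), 100, "iv")
  expect_equal(res$MRT, 1 / k10, tolerance = 0.01)
  expect_equal(res$Vss, 8, tolerance = 0.01)
  expect_equal(res$CL, 0.4, tolerance = 0.005)
})

test_that("dose scaling leaves clearance invariant", {
  th <- ref_theta()
  tms <- c(1 / 120, 0.25, 0.5, 1, 2, 4, 6, 8, 24)
  r1 <- nca_profile(tms, conc_iv_bolus(th, 100, tms), 100, "iv")
  r2 <- nca_profile(tms, conc_iv_bolus(th, 200, tms), 200, "iv")
  expect_equal(r2$AUC_inf, 2 * r1$AUC_inf, tolerance = 1e-9)
  expect_equal(r2$CL, r1$CL, tolerance = 1e-9)
})

test_that("dense profile recovers Vss = Vc + VP within 2%", {
  th <- ref_theta()
  m <- macro_to_micro(th)
  tms <- seq(0.001, 15 / m$beta, by = 0.02)
  res <- nca_profile(tms, conc_iv_bolus(th, 126, tms), 126, "iv")
  expect_equal(res$Vss, th$Vc + th$VP, tolerance = 0.02)
  expect_equal(res$CL, th$CL, tolerance = 0.02)
})

test_that("bioavailability", {
  expect_equal(bioavailability(100, 10, 100, 10), 100)
  expect_equal(bioavailability(90, 10, 100, 10), 90)
  expect_error(bioavailability(0, 10, 100, 10), "positive")
  # round trip on dense noise-free profiles from the generative values
  th <- ref_theta()
  m <- macro_to_micro(th)
  tms <- seq(0.001, 15 / m$beta, by = 0.02)
  iv <- nca_profile(tms, conc_iv_bolus(th, 126, tms), 126, "iv")
  im <- nca_profile(tms, conc_first_order_abs(th, 126, tms), 126, "im")
  expect_equal(bioavailability(im$AUC_inf, 126, iv$AUC_inf, 126), 90.80,
               tolerance = 0.02)
})

test_that("noise-free dense recovery holds across random parameter sets", {
  set.seed(606)
  for (i in 1:5) {
    th <- random_theta()
    m <- macro_to_micro(th)
    tms <- seq(0.001, 15 / m$beta, length.out = 40000)
    iv <- nca_profile(tms, conc_iv_bolus(th, 100, tms), 100, "iv")
    im <- nca_profile(tms, conc_first_order_abs(th, 100, tms), 100, "im")
    expect_equal(iv$CL, th$CL, tolerance = 0.02)
    expect_equal(iv$Vss, th$Vc + th$VP, tolerance = 0.02)
    expect_equal(bioavailability(im$AUC_inf, 100, iv$AUC_inf, 100),
                 100 * th$F, tolerance = 0.02)
  }
})

test_that("extrapolated fraction shrinks as sampling extends", {
  th <- ref_theta()
  ext <- vapply(c(24, 48, 96, 240, 480), function(t_end) {
    tms <- seq(0.01, t_end, length.out = 400)
    nca_profile(tms, conc_iv_bolus(th, 126, tms), 126, "iv")$AUC_extrap_pct
  }, numeric(1))
  expect_true(all(diff(ext) < 0))
})

test_that("study-design sampling leaves a large extrapolated area after IV", {
  # last sample (24 h) is well below 3 terminal half-lives (~80 h)
  th <- ref_theta()
  tms <- c(1 / 120, 0.25, 0.5, 1, 2, 4, 6, 8, 24)
  res <- nca_profile(tms, conc_iv_bolus(th, 126, tms), 126, "iv")
  expect_gt(res$AUC_extrap_pct, 30)
})

test_that("run_nca and nca_summary are consistent with per-subject recomputation", {
  ev <- generate_study(study_design(n_subjects = 3),
                       generative_model(sigma_prop = 0.05), seed = 21)
  res <- run_nca(ev)
  expect_true(all(res$status[res$route == "iv"] == "ok"))
  # per-subject recomputation oracle
  sub <- ev[ev$ID == 2 & ev$ROUTE == 1 & ev$EVID == 0 & ev$BLANK == 0, ]
  dose <- ev$AMT[ev$ID == 2 & ev$ROUTE == 1 & ev$EVID == 1]
  ref <- nca_profile(sub$TIME, sub$DV, dose, "iv", bw = sub$BW[1])
  got <- res[res$ID == 2 & res$route == "iv", ]
  expect_equal(got$AUC_inf, ref$AUC_inf)
  expect_equal(got$CL, ref$CL)
  summ <- nca_summary(res)
  cl_rows <- res$CL[res$route == "iv"]
  expect_equal(summ$mean[summ$route == "iv" & summ$parameter == "CL"],
               mean(cl_rows))
  expect_equal(summ$sd[summ$route == "iv" & summ$parameter == "CL"],
               stats::sd(cl_rows))
  # single subject: SD blank; identical subjects: SD zero
  one <- nca_summary(res[res$ID == 1 & res$route == "iv", ])
  expect_true(is.na(one$sd[one$parameter == "CL"]))
  two <- nca_summary(rbind(got, got))
  expect_equal(two$sd[two$parameter == "CL"], 0)
  # Cmax is an observed concentration; Tmax summarized as median (range)
  expect_true(got$Cmax %in% sub$DV)
  expect_match(summ$summary[summ$parameter == "Tmax" & summ$route == "im"],
               "\\(")
})
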