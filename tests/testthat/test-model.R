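# Structural model: micro-constant conversion, closed forms vs the
# matrix-exponential oracle, linearity, terminal behaviour, superposition.

test_that("macro_to_micro matches the eigenvalue oracle and its identities", {
  th <- ref_theta()
  m <- macro_to_micro(th)
  ev <- oracle_disposition_rates(th)
  expect_equal(m$alpha, ev[1], tolerance = 1e-10)
  expect_equal(m$beta, ev[2], tolerance = 1e-10)
  expect_equal(m$A + m$B, 1 / th$Vc, tolerance = 1e-12)

  set.seed(101)
  for (i in 1:100) {
    th_i <- random_theta()
    m_i <- macro_to_micro(th_i)
    expect_lt(abs(m_i$alpha * m_i$beta - m_i$k10 * m_i$k21) /
                (m_i$k10 * m_i$k21), 1e-10)
    expect_lt(abs(m_i$alpha + m_i$beta - (m_i$k10 + m_i$k12 + m_i$k21)) /
                (m_i$k10 + m_i$k12 + m_i$k21), 1e-12)
    expect_true(m_i$alpha >= m_i$beta, info = "root ordering")
  }
})

test_that("CLD -> 0 collapses to the one-compartment limit", {
  m <- macro_to_micro(theta_fixed(CL = 0.255, Vc = 7.11, CLD = 0, VP = 2.51,
                                  Ka = 0.471, F = 0.908))
  expect_equal(m$k12, 0)
  # the surviving disposition rate is the elimination constant CL/Vc
  expect_equal(m$alpha, 0.255 / 7.11, tolerance = 1e-12)
  expect_equal(m$B, 0, tolerance = 1e-15)
  expect_equal(m$A, 1 / 7.11, tolerance = 1e-12)
})

test_that("theta_fixed validates its domain", {
  expect_error(theta_fixed(-1, 7, 127, 2.5, 0.5, 0.9), "positive")
  expect_error(theta_fixed(0.2, 7, 127, 2.5, 0.5, 1.2), "exceed 1")
  expect_error(theta_fixed(0.2, 7, NA, 2.5, 0.5, 0.9), "finite")
})

test_that("conc_iv_bolus agrees with the matrix-exponential oracle", {
  th <- ref_theta()
  expect_equal(conc_iv_bolus(th, 126, 0), 126 / th$Vc, tolerance = 1e-12)
  expect_equal(conc_iv_bolus(th, 0, c(0, 1, 5)), c(0, 0, 0))
  expect_error(conc_iv_bolus(th, 126, -1), "non-negative")
  tms <- c(0.1, 1, 24)
  expect_equal(conc_iv_bolus(th, 126, tms), oracle_conc(th, 126, "iv", tms),
               tolerance = 1e-8)
})

test_that("conc_first_order_abs agrees with the depot oracle", {
  th <- ref_theta()
  expect_identical(conc_first_order_abs(th, 126, 0), 0)
  tms <- c(1, 4, 8, 24, 48)
  expect_equal(conc_first_order_abs(th, 126, tms),
               oracle_conc(th, 126, "im", tms), tolerance = 1e-8)
})

test_that("very fast absorption converges to availability-scaled bolus", {
  th <- ref_theta()
  m <- macro_to_micro(th)
  th_fast <- theta_fixed(th$CL, th$Vc, th$CLD, th$VP, Ka = 1e4 * m$alpha,
                         F = th$F)
  tms <- seq(0.1, 24, by = 0.5)
  expect_equal(conc_first_order_abs(th_fast, 126, tms),
               th$F * conc_iv_bolus(th, 126, tms), tolerance = 0.01)
})

test_that("closed form matches the ODE oracle for random parameter sets", {
  set.seed(202)
  tms <- c(0.05, 0.5, 2, 8, 30)
  for (i in 1:100) {
    th <- random_theta()
    for (rt in c("iv", "im")) {
      f <- if (rt == "iv") conc_iv_bolus else conc_first_order_abs
      got <- f(th, 100, tms)
      ref <- oracle_conc(th, 100, rt, tms)
      expect_lt(max(abs(got - ref) / pmax(abs(ref), 1e-12)), 1e-6)
    }
  }
})

test_that("concentration is homogeneous of degree 1 in dose", {
  set.seed(303)
  tms <- c(0.1, 1, 10, 40)
  for (i in 1:20) {
    th <- random_theta()
    expect_equal(conc_iv_bolus(th, 250, tms), 2.5 * conc_iv_bolus(th, 100, tms),
                 tolerance = 1e-12)
    expect_equal(conc_first_order_abs(th, 250, tms),
                 2.5 * conc_first_order_abs(th, 100, tms), tolerance = 1e-12)
  }
})

test_that("terminal log-slope equals -beta on both routes", {
  set.seed(404)
  for (i in 1:20) {
    th <- random_theta()
    m <- macro_to_micro(th)
    if (th$Ka <= 1.5 * m$beta) next   # terminal phase must be disposition
    # time after which every faster exponential is < 1e-6 of the beta term
    decay_t <- function(coef_ratio, rate)
      (log(pmax(abs(coef_ratio), 1e-6)) + 14) / (rate - m$beta)
    t0 <- max(decay_t(m$A / m$B, m$alpha),
              decay_t(1, th$Ka), 10 / m$alpha)
    tms <- t0 + c(0, 1, 2) / m$beta
    for (rt in c("iv", "im")) {
      f <- if (rt == "iv") conc_iv_bolus else conc_first_order_abs
      cc <- f(th, 100, tms)
      slope <- (log(cc[3]) - log(cc[1])) / (tms[3] - tms[1])
      expect_equal(-slope, m$beta, tolerance = 1e-3)
    }
  }
})

test_that("quadrature AUC(0, Inf) equals dose/CL (IV) and F dose/CL (IM)", {
  set.seed(505)
  for (i in 1:10) {
    th <- random_theta()
    a_iv <- stats::integrate(function(t) conc_iv_bolus(th, 100, t), 0, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(a_iv, 100 / th$CL, tolerance = 1e-6)
    a_im <- stats::integrate(function(t) conc_first_order_abs(th, 100, t),
                             0, Inf, rel.tol = 1e-10)$value
    expect_equal(a_im, th$F * 100 / th$CL, tolerance = 1e-6)
  }
})

test_that("superpose reduces to single-dose and is additive", {
  th <- ref_theta()
  tg <- c(0.5, 2, 10, 30)
  one <- superpose(dose_events(0, 126, "im"), th, tg)
  expect_equal(one$conc, conc_first_order_abs(th, 126, tg))

  ev <- dose_events(c(0, 24), c(126, 126), "iv")
  got <- superpose(ev, th, c(24.5, 30, 47))
  ref <- oracle_conc_multi(th, ev, c(24.5, 30, 47))
  expect_equal(got$conc, ref, tolerance = 1e-7)

  expect_warning(
    superpose(data.frame(time = c(24, 0), amount = c(126, 126),
                         route = "iv"), th, tg),
    "reordering")
})

test_that("q24 trough accumulation follows the geometric series", {
  th <- ref_theta()
  m <- macro_to_micro(th)
  ev <- dose_events(seq(0, by = 24, length.out = 10), 126, "im")
  trough10 <- superpose(ev, th, 10 * 24)$conc
  trough1 <- conc_first_order_abs(th, 126, 24)
  r_expected <- (1 - exp(-10 * m$beta * 24)) / (1 - exp(-m$beta * 24))
  expect_equal(trough10 / trough1, r_expected, tolerance = 0.02)
})
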