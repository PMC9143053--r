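#' Two-compartment disposition parameters
#'
#' Constructs and validates the fixed-effect parameter set of the structural
#' model: linear two-compartment disposition with elimination from the central
#' compartment and, for the intramuscular route, first-order absorption from a
#' depot. Units are fixed package-wide: time in hours, amounts in mg, volumes
#' in litres, concentrations in mg/L (numerically identical to ug/mL) and rate
#' constants in 1/h.
#'
#' @param CL plasma (elimination) clearance, L/h.
#' @param Vc central distribution volume, L.
#' @param CLD intercompartmental (distribution) clearance, L/h. `CLD = 0` is
#'   accepted as the degenerate one-compartment limit.
#' @param VP peripheral distribution volume, L.
#' @param Ka first-order absorption rate constant, 1/h.
#' @param F absolute bioavailability of the extravascular route, a fraction in
#'   (0, 1]. Intravenous doses always have unit availability.
#' @return An object of class `theta_fixed` (a named list).
#' @examples
#' th <- theta_fixed(CL = 0.255, Vc = 7.11, CLD = 127, VP = 2.51,
#'                   Ka = 0.471, F = 0.908)
#' conc_iv_bolus(th, dose = 126, t = c(0, 1, 24))
#' @export
theta_fixed <- function(CL, Vc, CLD, VP, Ka, F) {
  vals <- c(CL = unname(CL), Vc = unname(Vc), CLD = unname(CLD),
            VP = unname(VP), Ka = unname(Ka), F = unname(F))
  if (any(!is.finite(vals)))
    stop("all structural parameters must be finite", call. = FALSE)
  strict <- vals[c("CL", "Vc", "VP", "Ka", "F")]
  if (any(strict <= 0))
    stop("CL, Vc, VP, Ka and F must be strictly positive", call. = FALSE)
  if (CLD < 0)
    stop("CLD must be non-negative", call. = FALSE)
  if (F > 1)
    stop("bioavailability F must not exceed 1", call. = FALSE)
  structure(as.list(vals), class = "theta_fixed")
}

#' @export
print.theta_fixed <- function(x, ...) {
  cat("Two-compartment fixed effects (h, mg, L):\n")
  print(unlist(x))
  invisible(x)
}

#' Convert macro parameters to micro rate constants
#'
#' Reparameterizes clearances/volumes into the first-order micro constants
#' `k10 = CL/Vc`, `k12 = CLD/Vc`, `k21 = CLD/VP`, the hybrid disposition rates
#' `alpha >= beta` (roots of `s^2 - (k10+k12+k21) s + k10 k21 = 0`) and the
#' macro intercepts `A`, `B` of the unit intravenous bolus response
#' `C(t) = A exp(-alpha t) + B exp(-beta t)`, so that `A + B = 1/Vc`.
#'
#' @param theta a [theta_fixed()] object.
#' @return An object of class `micro_params` with fields `k10`, `k12`, `k21`,
#'   `alpha`, `beta`, `A`, `B`.
#' @export
macro_to_micro <- function(theta) {
  theta <- as_theta(theta)
  m <- .micro_vec(theta$CL, theta$Vc, theta$CLD, theta$VP)
  structure(list(k10 = m$k10, k12 = m$k12, k21 = m$k21,
                 alpha = m$alpha, beta = m$beta, A = m$A, B = m$B),
            class = "micro_params")
}

as_theta <- function(theta) {
  if (inherits(theta, "theta_fixed")) return(theta)
  req <- c("CL", "Vc", "CLD", "VP", "Ka", "F")
  if (is.list(theta) && all(req %in% names(theta)))
    return(do.call(theta_fixed, theta[req]))
  if (is.numeric(theta) && all(req %in% names(theta)))
    return(do.call(theta_fixed, as.list(theta[req])))
  stop("cannot interpret `theta`: need fields ", paste(req, collapse = ", "),
       call. = FALSE)
}

# Vectorized micro-constant computation shared by the scalar user API and the
# population machinery (all arguments may be vectors of equal length).
.micro_vec <- function(CL, Vc, CLD, VP) {
  k10 <- CL / Vc
  k12 <- CLD / Vc
  k21 <- CLD / VP
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  # disc = (k10+k12-k21)^2 + 2*k12*k21 + ... >= 0 for positive rates
  stopifnot(all(disc >= -1e-12 * s^2))
  root <- sqrt(pmax(disc, 0))
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  denom <- Vc * (alpha - beta)
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta,
       A = (alpha - k21) / denom, B = (k21 - beta) / denom, Vc = Vc)
}

# N x T concentration matrices (parameters vectorized across rows).
.conc_iv_mat <- function(m, dose, times) {
  dose * (m$A * exp(-outer(m$alpha, times)) + m$B * exp(-outer(m$beta, times)))
}

.conc_im_mat <- function(m, Ka, F, dose, times) {
  # guard coincident rates: perturb Ka rather than switching to the
  # t*exp(-kt) confluent form (indistinguishable at data noise levels)
  clash <- (abs(Ka - m$alpha) < 1e-9 * m$alpha) |
    (abs(Ka - m$beta) < 1e-9 * pmax(m$beta, .Machine$double.xmin))
  if (any(clash)) Ka <- ifelse(clash, Ka * (1 + 1e-6), Ka)
  c1 <- (m$k21 - m$alpha) / ((Ka - m$alpha) * (m$beta - m$alpha))
  c2 <- (m$k21 - m$beta) / ((Ka - m$beta) * (m$alpha - m$beta))
  c3 <- (m$k21 - Ka) / ((m$alpha - Ka) * (m$beta - Ka))
  scale <- F * dose * Ka / m$Vc
  scale * (c1 * exp(-outer(m$alpha, times)) +
           c2 * exp(-outer(m$beta, times)) +
           c3 * exp(-outer(Ka, times)))
}

#' Concentration after an intravenous bolus
#'
#' Closed-form plasma concentration of the two-compartment model after an
#' instantaneous intravenous bolus at `t = 0`:
#' `C(t) = dose (A exp(-alpha t) + B exp(-beta t))`.
#'
#' @inheritParams macro_to_micro
#' @param dose dose amount, mg.
#' @param t time(s) after the dose, h (vectorized, all `>= 0`).
#' @return Concentrations in ug/mL (= mg/L), same length as `t`.
#' @export
conc_iv_bolus <- function(theta, dose, t) {
  theta <- as_theta(theta)
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  m <- .micro_vec(theta$CL, theta$Vc, theta$CLD, theta$VP)
  drop(.conc_iv_mat(m, dose, as.numeric(t)))
}

#' Concentration after a first-order-absorption (intramuscular) dose
#'
#' Closed-form plasma concentration when the dose enters a depot compartment
#' with availability `F` and is absorbed with first-order rate `Ka`; `C(0) = 0`
#' and the profile is the standard three-exponential form. If `Ka` coincides
#' with a disposition rate within 1e-9 relative, `Ka` is perturbed by 1e-6
#' relative (the confluent limit is not evaluated).
#'
#' @inheritParams conc_iv_bolus
#' @return Concentrations in ug/mL, same length as `t`.
#' @export
conc_first_order_abs <- function(theta, dose, t) {
  theta <- as_theta(theta)
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  m <- .micro_vec(theta$CL, theta$Vc, theta$CLD, theta$VP)
  drop(.conc_im_mat(m, theta$Ka, theta$F, dose, as.numeric(t)))
}

#' Dose event table
#'
#' @param time dose times, h (non-negative).
#' @param amount dose amounts, mg (non-negative).
#' @param route `"iv"` (central bolus) or `"im"` (first-order depot),
#'   recycled as needed.
#' @return A `data.frame` with columns `time`, `amount`, `route`.
#' @export
dose_events <- function(time, amount, route) {
  route <- match.arg(tolower(route), c("iv", "im"), several.ok = TRUE)
  if (any(time < 0) || any(amount < 0))
    stop("dose times and amounts must be non-negative", call. = FALSE)
  data.frame(time = time, amount = amount,
             route = rep_len(route, length(time)))
}

#' Superpose single-dose profiles over a dosing history
#'
#' The model is linear, so the concentration under any dosing history is the
#' sum of single-dose contributions from all doses given at or before each
#' evaluation time.
#'
#' @inheritParams conc_iv_bolus
#' @param events a [dose_events()] table.
#' @param t_grid evaluation times, h.
#' @return A `data.frame` with columns `time` and `conc` (ug/mL).
#' @export
superpose <- function(events, theta, t_grid) {
  theta <- as_theta(theta)
  stopifnot(is.data.frame(events),
            all(c("time", "amount", "route") %in% names(events)))
  if (is.unsorted(events$time)) {
    warning("dose events were not time-sorted; reordering")
    events <- events[order(events$time), , drop = FALSE]
  }
  conc <- numeric(length(t_grid))
  for (i in seq_len(nrow(events))) {
    rel <- t_grid - events$time[i]
    on <- rel >= 0
    if (!any(on)) next
    f <- if (events$route[i] == "iv") conc_iv_bolus else conc_first_order_abs
    conc[on] <- conc[on] + f(theta, events$amount[i], rel[on])
  }
  data.frame(time = t_grid, conc = conc)
}
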