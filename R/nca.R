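# Non-compartmental analysis: terminal-slope regression, linear/log
# trapezoidal areas, statistical moments, volumes and bioavailability.

#' Terminal slope (lambda-z) regression
#'
#' Ordinary least squares of `log(conc)` on time over terminal point subsets.
#' Candidate subsets are the contiguous windows that end at the last sample,
#' contain at least `min_points` points and start strictly after the observed
#' peak; the window maximizing the adjusted R-squared is selected (ties within
#' 1e-4 go to the longer window). This mirrors common automated "best fit"
#' practice and is deterministic.
#'
#' @param times,concs observation times (h) and concentrations (ug/mL).
#' @param min_points minimum number of regression points (default 3).
#' @return A list with `lambda_z` (1/h), `intercept` (log scale),
#'   `n_points`, `r2_adj`, `c_last_pred` (regression prediction at the last
#'   time) and `status` (`"ok"`, `"insufficient_points"` or
#'   `"nonpositive_slope"`). On failure the numeric fields are `NA`.
#' @export
fit_lambda_z <- function(times, concs, min_points = 3) {
  stopifnot(length(times) == length(concs), min_points >= 3)
  ok <- is.finite(concs) & concs > 0
  times <- times[ok]; concs <- concs[ok]
  n <- length(times)
  failed <- function(status) list(lambda_z = NA_real_, intercept = NA_real_,
                                  n_points = NA_integer_, r2_adj = NA_real_,
                                  c_last_pred = NA_real_, status = status)
  i_max <- which.max(concs)            # earliest index at ties
  if (i_max + min_points > n) return(failed("insufficient_points"))
  starts <- seq(i_max + 1L, n - min_points + 1L)
  # suffix-window OLS statistics in one pass (reverse cumulative sums), with
  # centred x/y for conditioning; the selected window is refit exactly below
  xx <- times - mean(times[starts[1]:n])
  yy <- log(concs) - mean(log(concs[starts[1]:n]))
  rc <- function(v) rev(cumsum(rev(v)))
  k <- n - starts + 1
  Sx <- rc(xx)[starts]; Sy <- rc(yy)[starts]
  Sxx <- rc(xx^2)[starts]; Syy <- rc(yy^2)[starts]; Sxy <- rc(xx * yy)[starts]
  num <- k * Sxy - Sx * Sy
  den_x <- k * Sxx - Sx^2
  den_y <- k * Syy - Sy^2
  r2 <- ifelse(den_y > 0, num^2 / (den_x * den_y), 1)
  r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
  # longest window whose adjusted R-squared is within 1e-4 of the best
  s_best <- starts[which(r2a >= max(r2a) - 1e-4)[1]]
  idx <- s_best:n
  ft <- stats::lm.fit(cbind(1, times[idx]), log(concs[idx]))
  slope <- unname(ft$coefficients[2])
  if (!is.finite(slope) || slope >= 0) return(failed("nonpositive_slope"))
  list(lambda_z = -slope, intercept = unname(ft$coefficients[1]),
       n_points = length(idx),
       r2_adj = r2a[match(s_best, starts)],
       c_last_pred = unname(exp(ft$coefficients[1] + slope * times[n])),
       status = "ok")
}

#' Half-life from a first-order rate constant
#'
#' `log(2) / k`. The natural logarithm of 2 is used internally; the common
#' 0.693 shorthand is a display convention only.
#'
#' @param k first-order rate constant(s), 1/h, strictly positive.
#' @return Half-life in h.
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("rate constant must be strictly positive", call. = FALSE)
  log(2) / k
}

# shared interval rule: linear trapezoid on non-decreasing (or degenerate)
# segments, logarithmic trapezoid on strictly decreasing positive segments
.linlog_terms <- function(times, concs) {
  n <- length(times)
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  t1 <- times[i1]; t2 <- times[i2]; c1 <- concs[i1]; c2 <- concs[i2]
  dt <- t2 - t1
  log_ok <- c1 > 0 & c2 > 0 & c2 < c1
  if (any(c1 < 0 | c2 < 0))
    warning("negative concentrations: affected intervals use the linear rule")
  auc <- ifelse(log_ok, dt * (c1 - c2) / log(c1 / c2), dt * (c1 + c2) / 2)
  k <- log(pmax(c1, 1e-300) / pmax(c2, 1e-300)) / dt
  aumc <- ifelse(log_ok,
                 (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2,
                 dt * (t1 * c1 + t2 * c2) / 2)
  list(auc = auc, aumc = aumc)
}

#' Area under the curve by the linear/log trapezoidal rule
#'
#' Linear trapezoid on intervals where concentration is non-decreasing (or a
#' value is non-positive), logarithmic trapezoid
#' `dt (C1 - C2) / log(C1 / C2)` where it is strictly decreasing.
#'
#' @param times strictly increasing times, h.
#' @param concs concentrations, ug/mL.
#' @return AUC from the first to the last time, ug*h/mL.
#' @export
auc_linlog <- function(times, concs) {
  stopifnot(length(times) == length(concs), length(times) >= 2)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  sum(.linlog_terms(times, concs)$auc)
}

#' First-moment area (AUMC) by the linear/log trapezoidal rule
#'
#' @inheritParams auc_linlog
#' @return AUMC from the first to the last time, ug*h^2/mL.
#' @export
aumc_linlog <- function(times, concs) {
  stopifnot(length(times) == length(concs), length(times) >= 2)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  sum(.linlog_terms(times, concs)$aumc)
}

#' Extrapolate an AUC to infinity
#'
#' `AUC_inf = AUC_t + C_last_pred / lambda_z`, where `C_last_pred` is the
#' terminal-regression prediction at the last sampling time. The extrapolated
#' percentage is reported relative to `AUC_inf`.
#'
#' @param auc_t observed-range AUC, ug*h/mL.
#' @param c_last_pred predicted concentration at the last sample, ug/mL.
#' @param lambda_z terminal rate constant, 1/h (> 0).
#' @return List with `auc_inf`, `extrap_pct` and `valid` (FALSE when the
#'   whole area is extrapolated).
#' @export
auc_extrapolate <- function(auc_t, c_last_pred, lambda_z) {
  if (lambda_z <= 0) stop("lambda_z must be strictly positive", call. = FALSE)
  tail_area <- c_last_pred / lambda_z
  auc_inf <- auc_t + tail_area
  extrap <- if (auc_inf > 0) 100 * tail_area / auc_inf else NA_real_
  valid <- is.finite(extrap) && extrap < 100
  if (!valid) warning("AUC is fully extrapolated; result flagged invalid")
  list(auc_inf = auc_inf, extrap_pct = extrap, valid = valid)
}

#' Absolute bioavailability from dose-normalized AUC ratio
#'
#' @param auc_im,auc_iv AUC to infinity after the extravascular and
#'   intravenous doses, ug*h/mL.
#' @param dose_im,dose_iv corresponding doses, mg.
#' @return Bioavailability in percent.
#' @export
bioavailability <- function(auc_im, dose_im, auc_iv, dose_iv) {
  if (any(c(auc_im, dose_im, auc_iv, dose_iv) <= 0))
    stop("AUCs and doses must be strictly positive", call. = FALSE)
  100 * (auc_im / dose_im) / (auc_iv / dose_iv)
}

#' Non-compartmental analysis of a single profile
#'
#' Computes the full per-profile parameter set: terminal slope and half-life,
#' observed and extrapolated areas, first-moment area and mean residence time,
#' peak metrics and -- for intravenous profiles -- clearance and the
#' distribution volumes `Vss = CL * MRT`, `Vdarea = dose / (AUC * lambda_z)`
#' and the initial volume `Vi = dose / C(0)` with `C(0)` back-extrapolated
#' log-linearly from the first two samples. For extravascular profiles a zero
#' concentration at `t = 0` opens the AUC and the volume/clearance fields are
#' left empty. The moment tail uses
#' `C_last_pred * t_last / lambda_z + C_last_pred / lambda_z^2`.
#'
#' @param times,concs the observed profile (post-dose times, h; ug/mL).
#' @param dose administered dose, mg.
#' @param route `"iv"` or `"im"`.
#' @param bw optional bodyweight, kg; adds per-kg clearance (mL/h/kg) and
#'   volumes (L/kg).
#' @param min_points passed to [fit_lambda_z()].
#' @return One-row data.frame (an `NCAResult`).
#' @export
nca_profile <- function(times, concs, dose, route = c("iv", "im"), bw = NULL,
                        min_points = 3) {
  route <- match.arg(route)
  stopifnot(length(times) == length(concs), dose > 0)
  o <- order(times)
  times <- times[o]; concs <- concs[o]
  lz <- fit_lambda_z(times, concs, min_points)
  i_max <- which.max(concs)
  cmax <- concs[i_max]; tmax <- times[i_max]
  a_times <- times; a_concs <- concs
  if (route == "im" && times[1] > 0) {
    a_times <- c(0, times); a_concs <- c(0, concs)
  }
  auc_t <- auc_linlog(a_times, a_concs)
  aumc_t <- aumc_linlog(a_times, a_concs)
  out <- data.frame(
    route = route, status = lz$status,
    lambda_z = lz$lambda_z,
    t_half_z = if (lz$status == "ok") half_life(lz$lambda_z) else NA_real_,
    n_points_lambda_z = lz$n_points, r2_adj = lz$r2_adj,
    AUC_t = auc_t, AUC_inf = NA_real_, AUC_extrap_pct = NA_real_,
    AUMC = NA_real_, MRT = NA_real_,
    Cmax = cmax, Tmax = tmax, Cmax_over_AUC = NA_real_,
    CL = NA_real_, Vss = NA_real_, Vdarea = NA_real_, Vi = NA_real_,
    CL_mL_h_kg = NA_real_, Vss_L_kg = NA_real_, Vdarea_L_kg = NA_real_,
    Vi_L_kg = NA_real_, F_pct = NA_real_)
  if (lz$status != "ok") return(out)
  ext <- auc_extrapolate(auc_t, lz$c_last_pred, lz$lambda_z)
  t_last <- a_times[length(a_times)]
  aumc_inf <- aumc_t + lz$c_last_pred * t_last / lz$lambda_z +
    lz$c_last_pred / lz$lambda_z^2
  out$AUC_inf <- ext$auc_inf
  out$AUC_extrap_pct <- ext$extrap_pct
  out$AUMC <- aumc_inf
  out$MRT <- aumc_inf / ext$auc_inf
  out$Cmax_over_AUC <- cmax / ext$auc_inf
  if (route == "iv") {
    cl <- dose / ext$auc_inf
    out$CL <- cl
    out$Vss <- cl * out$MRT
    out$Vdarea <- dose / (ext$auc_inf * lz$lambda_z)
    c0 <- if (length(times) >= 2 && concs[1] > concs[2] && concs[2] > 0)
      exp(log(concs[1]) - times[1] *
            (log(concs[2]) - log(concs[1])) / (times[2] - times[1]))
    else concs[1]
    out$Vi <- dose / c0
    if (!is.null(bw)) {
      out$CL_mL_h_kg <- 1000 * cl / bw
      out$Vss_L_kg <- out$Vss / bw
      out$Vdarea_L_kg <- out$Vdarea / bw
      out$Vi_L_kg <- out$Vi / bw
    }
  }
  out
}

#' Non-compartmental analysis of an event table
#'
#' Runs [nca_profile()] for every subject and route in an event table
#' (dose rows `EVID = 1`, observation rows `EVID = 0`, blanks excluded) and
#' attaches the per-subject absolute bioavailability to the intramuscular
#' results.
#'
#' @param events an `event_table` (see [generate_study()] / [read_events()]).
#' @param min_points passed to [fit_lambda_z()].
#' @return A data.frame of per-subject, per-route `NCAResult` rows with
#'   leading columns `ID`, `dose` and `bw`.
#' @export
run_nca <- function(events, min_points = 3) {
  stopifnot(is.data.frame(events))
  out <- list()
  for (id in unique(events$ID)) {
    sub <- events[events$ID == id, , drop = FALSE]
    res_iv <- NULL
    for (rt in intersect(c(1, 2), unique(sub$ROUTE))) {
      blk <- sub[sub$ROUTE == rt, , drop = FALSE]
      dose <- sum(blk$AMT[blk$EVID == 1])
      obs <- blk[blk$EVID == 0 & blk$BLANK == 0, , drop = FALSE]
      if (dose <= 0 || nrow(obs) < 3) next
      rt_lbl <- if (rt == 1) "iv" else "im"
      res <- nca_profile(obs$TIME, obs$DV, dose, rt_lbl, bw = blk$BW[1],
                         min_points = min_points)
      res <- cbind(data.frame(ID = id, dose = dose, bw = blk$BW[1]), res)
      if (rt == 1) res_iv <- res
      if (rt == 2 && !is.null(res_iv) &&
          is.finite(res$AUC_inf) && is.finite(res_iv$AUC_inf))
        res$F_pct <- bioavailability(res$AUC_inf, dose,
                                     res_iv$AUC_inf, res_iv$dose)
      out[[length(out) + 1L]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Study-level NCA summary
#'
#' Mean and SD of every numeric NCA parameter per route; the time to peak is
#' summarized as median (range), the usual convention for that parameter.
#' With a single subject the SD is left blank; the single-subject median
#' equals the value itself.
#'
#' @param results output of [run_nca()].
#' @return A data.frame with columns `route`, `parameter`, `mean`, `sd`,
#'   `summary` (formatted) and `n`.
#' @export
nca_summary <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  params <- setdiff(names(results)[vapply(results, is.numeric, TRUE)],
                    c("ID", "n_points_lambda_z"))
  out <- list()
  for (rt in unique(results$route)) {
    blk <- results[results$route == rt, , drop = FALSE]
    for (p in params) {
      x <- blk[[p]]
      x <- x[is.finite(x)]
      if (!length(x)) next
      if (p == "Tmax") {
        s <- sprintf("%.2f (%.2f-%.2f)", stats::median(x), min(x), max(x))
        out[[length(out) + 1L]] <- data.frame(
          route = rt, parameter = p, mean = stats::median(x),
          sd = NA_real_, summary = s, n = length(x))
      } else {
        sdv <- if (length(x) > 1) stats::sd(x) else NA_real_
        s <- if (is.na(sdv)) sprintf("%.4g", mean(x))
             else sprintf("%.4g ± %.4g", mean(x), sdv)
        out[[length(out) + 1L]] <- data.frame(
          route = rt, parameter = p, mean = mean(x), sd = sdv,
          summary = s, n = length(x))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
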