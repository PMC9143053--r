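# Bioanalytical validation statistics (linearity, repeatability, accuracy,
# signal-to-noise based LOD/LOQ) and tissue-recovery summaries with an exact
# Mann-Whitney test.

#' Calibration-curve linearity
#'
#' Least-squares regression of signal on nominal concentration; the method
#' passes linearity when R-squared exceeds 0.99.
#'
#' @param nominal nominal concentrations, ppb (at least 3 distinct levels).
#' @param signal measured responses.
#' @return List with `slope`, `intercept`, `r_squared`, `pass`.
#' @export
fit_calibration <- function(nominal, signal) {
  stopifnot(length(nominal) == length(signal), all(nominal > 0))
  if (length(unique(nominal)) < 3)
    stop("calibration needs at least 3 distinct levels", call. = FALSE)
  ft <- stats::lm.fit(cbind(1, nominal), signal)
  r2 <- 1 - sum(ft$residuals^2) / sum((signal - mean(signal))^2)
  list(slope = unname(ft$coefficients[2]),
       intercept = unname(ft$coefficients[1]),
       r_squared = r2, pass = r2 > 0.99)
}

#' Repeatability statistics of replicate injections
#'
#' Mean, sample standard deviation (n - 1 denominator) and relative standard
#' deviation `RSD = 100 SD / mean` of replicate signals.
#'
#' @param x replicate measurements (at least 2).
#' @return List with `mean`, `sd`, `rsd_pct`, `n`.
#' @export
repeatability <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  s <- stats::sd(x)
  list(mean = m, sd = s,
       rsd_pct = if (m == 0) NA_real_ else 100 * s / m, n = length(x))
}

#' Relative standard deviation from summary statistics
#'
#' @param mean,sd summary mean and SD.
#' @return `100 * sd / mean`.
#' @export
rsd_from_summary <- function(mean, sd) {
  if (any(mean == 0)) stop("RSD undefined for zero mean", call. = FALSE)
  100 * sd / mean
}

#' Accuracy of back-calculated concentrations
#'
#' Recovery in percent, `100 * back_calculated / nominal`, with a per-level
#' summary (mean, SD, RSD) and the conventional 80-120% acceptance band.
#'
#' @param back_calculated interpolated concentrations.
#' @param nominal nominal concentrations (> 0), recycled against
#'   `back_calculated`.
#' @return List with `pct` (per-sample recoveries), `pass` (within 80-120,
#'   boundary inclusive) and `by_level` (data.frame of level, mean, sd,
#'   rsd_pct, n).
#' @export
accuracy <- function(back_calculated, nominal) {
  stopifnot(all(nominal > 0))
  nominal <- rep_len(nominal, length(back_calculated))
  pct <- 100 * back_calculated / nominal
  lv <- sort(unique(nominal))
  by_level <- do.call(rbind, lapply(lv, function(l) {
    p <- pct[nominal == l]
    data.frame(level = l, mean = mean(p),
               sd = if (length(p) > 1) stats::sd(p) else NA_real_,
               rsd_pct = if (length(p) > 1) 100 * stats::sd(p) / mean(p)
                         else NA_real_,
               n = length(p))
  }))
  list(pct = pct, pass = pct >= 80 & pct <= 120, by_level = by_level)
}

#' Signal-to-noise based detection and quantification limits
#'
#' Assuming a linear signal-concentration relation, the concentration at
#' which the peak height reaches three times (LOD) or ten times (LOQ) the
#' baseline noise: `LOD = 3 conc / (signal/noise)`,
#' `LOQ = 10 conc / (signal/noise)`.
#'
#' @param signal_height peak height at concentration `conc`.
#' @param noise_height baseline noise height (> 0).
#' @param conc concentration of the measured standard, ppb.
#' @return List with `lod_ppb`, `loq_ppb`, `snr`.
#' @export
lod_loq <- function(signal_height, noise_height, conc) {
  if (noise_height <= 0 || signal_height <= 0)
    stop("signal and noise heights must be strictly positive", call. = FALSE)
  snr <- signal_height / noise_height
  list(lod_ppb = 3 * conc / snr, loq_ppb = 10 * conc / snr, snr = snr)
}

#' Exact Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U test with mid-ranks for ties. For
#' `n_a + n_b <= 12` the null distribution is obtained by full enumeration of
#' all group assignments of the pooled (mid-)ranks and the two-sided p-value
#' is twice the smaller tail probability (capped at 1); for larger samples a
#' continuity-corrected normal approximation with tie correction is used.
#'
#' @param group_a,group_b numeric samples (each non-empty).
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact enumeration;
#'   default: exact for `n_a + n_b <= 12`.
#' @return List with `U` (statistic of group A), `p_value`, `method`.
#' @export
tissue_compare <- function(group_a, group_b, exact = NULL) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 1, nb >= 1)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)                        # mid-ranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(pooled)) == 1)
    return(list(U = U, p_value = 1, method = "degenerate"))
  if (is.null(exact)) exact <- na + nb <= 12
  if (exact) {
    combos <- utils::combn(na + nb, na)
    Us <- apply(combos, 2, function(idx)
      sum(r[idx]) - na * (na + 1) / 2)
    eps <- 1e-9
    p_lo <- mean(Us <= U + eps)
    p_hi <- mean(Us >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    list(U = U, p_value = p, method = "exact enumeration")
  } else {
    n <- na + nb
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    s2 <- na * nb / 12 * (n + 1 - tie_corr)
    z <- (abs(U - mu) - 0.5) / sqrt(s2)
    list(U = U, p_value = min(1, 2 * stats::pnorm(-z)),
         method = "normal approximation")
  }
}

#' Tissue-recovery summary
#'
#' Median (min, max) per tissue and the plasma/tissue concentration ratios.
#'
#' @param samples data.frame with columns `tissue` and `conc_ug_g`
#'   (as produced by [generate_tissue()]).
#' @param plasma_tissue name of the reference tissue for ratios
#'   (default "plasma"; ratios omitted when absent).
#' @return data.frame with `tissue`, `median`, `min`, `max`, `n`,
#'   `plasma_ratio`.
#' @export
tissue_summary <- function(samples, plasma_tissue = "plasma") {
  stopifnot(all(c("tissue", "conc_ug_g") %in% names(samples)))
  out <- do.call(rbind, lapply(unique(samples$tissue), function(ts) {
    x <- samples$conc_ug_g[samples$tissue == ts]
    data.frame(tissue = ts, median = stats::median(x), min = min(x),
               max = max(x), n = length(x))
  }))
  if (plasma_tissue %in% out$tissue) {
    pl <- out$median[out$tissue == plasma_tissue]
    out$plasma_ratio <- pl / out$median
  } else out$plasma_ratio <- NA_real_
  rownames(out) <- NULL
  out
}

#' Full validation report of a calibration/repeatability table
#'
#' Runs linearity on the pooled calibration rows, back-calculates every
#' calibration point through the fitted line for the accuracy summary and
#' computes repeatability statistics per level.
#'
#' @param cal a table from [generate_calibration()] (columns `kind`, `set`,
#'   `level_ppb`, `signal`).
#' @return List with `linearity`, `accuracy`, `repeatability` (data.frame per
#'   level).
#' @export
validation_report <- function(cal) {
  cc <- cal[cal$kind == "calibration", , drop = FALSE]
  lin <- fit_calibration(cc$level_ppb, cc$signal)
  back <- (cc$signal - lin$intercept) / lin$slope
  acc <- accuracy(back, cc$level_ppb)
  rp <- cal[cal$kind == "repeatability", , drop = FALSE]
  rep_tab <- if (nrow(rp)) do.call(rbind, lapply(
    sort(unique(rp$level_ppb)), function(l) {
      st <- repeatability(rp$signal[rp$level_ppb == l])
      data.frame(level_ppb = l, mean = st$mean, sd = st$sd,
                 rsd_pct = st$rsd_pct, n = st$n)
    })) else NULL
  list(linearity = lin, accuracy = acc, repeatability = rep_tab)
}
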