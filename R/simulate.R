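# Synthetic crossover studies, calibration/repeatability sets and tissue
# residue sets with the statistical structure the downstream analyses assume.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Crossover study design
#'
#' Describes the sampling design of the pig crossover study: every animal
#' receives an intravenous dose in period 1 and, after a washout, an
#' intramuscular dose in period 2, both at the same mg/kg level. Default
#' sampling times are 0.5 min, 15 min, 30 min and 1, 2, 4, 6, 8 and 24 h after
#' either dose, with an extra 48 h sample after the intramuscular dose. The
#' 0.5 min first sample is taken literally (1/120 h).
#'
#' @param n_subjects number of animals (default 4).
#' @param bw_range bodyweight range in kg, sampled uniformly (default 25-50).
#' @param dose_per_kg dose level in mg/kg for both routes (default 4).
#' @param iv_times,im_times post-dose sampling times, h, strictly increasing.
#' @param washout washout between periods, h (default 7 days; carryover is
#'   assumed fully eliminated, times restart at each dose).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 4,
                         bw_range = c(25, 50),
                         dose_per_kg = 4,
                         iv_times = c(1 / 120, 0.25, 0.5, 1, 2, 4, 6, 8, 24),
                         im_times = c(1 / 120, 0.25, 0.5, 1, 2, 4, 6, 8, 24, 48),
                         washout = 168) {
  stopifnot(n_subjects >= 1, length(bw_range) == 2, bw_range[1] <= bw_range[2],
            dose_per_kg > 0, washout >= 0)
  for (tt in list(iv_times, im_times))
    if (any(tt < 0) || is.unsorted(tt, strictly = TRUE))
      stop("sampling times must be non-negative and strictly increasing",
           call. = FALSE)
  structure(list(n_subjects = n_subjects, bw_range = bw_range,
                 dose_per_kg = dose_per_kg, iv_times = iv_times,
                 im_times = im_times, washout = washout),
            class = "study_design")
}

#' Generative population model
#'
#' The data-generating model of the synthetic-study module: typical values
#' `theta`, log-normal between-animal variability (one eta vector per animal,
#' shared across both crossover periods) and proportional residual error.
#' Parameters without an entry in `omega_sd` receive `fixed_omega_sd`
#' (default 0.15, i.e. omega^2 = 0.0225).
#'
#' @param theta a [theta_fixed()] object (default: published estimates).
#' @param omega_sd named log-scale SD vector for parameters with estimated
#'   variability (any of CL, Vc, CLD, VP, Ka, F).
#' @param fixed_omega_sd log-scale SD for the remaining parameters.
#' @param sigma_prop proportional residual SD (fraction, must be < 1).
#' @return An object of class `generative_model` with a full 6-vector
#'   `omega_sd` in canonical parameter order.
#' @export
generative_model <- function(theta = carprofen_reference()$theta,
                             omega_sd = carprofen_reference()$omega_sd,
                             fixed_omega_sd = 0.15,
                             sigma_prop = carprofen_reference()$sigma_prop) {
  theta <- as_theta(theta)
  if (sigma_prop < 0) stop("sigma_prop must be non-negative", call. = FALSE)
  if (sigma_prop >= 1)
    stop("sigma_prop >= 1 would generate negative concentrations; refusing",
         call. = FALSE)
  if (fixed_omega_sd < 0 || any(omega_sd < 0))
    stop("variability SDs must be non-negative", call. = FALSE)
  full <- rep(fixed_omega_sd, 6)
  names(full) <- .param_names
  if (length(omega_sd)) {
    bad <- setdiff(names(omega_sd), .param_names)
    if (length(bad)) stop("unknown parameter(s) in omega_sd: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    full[names(omega_sd)] <- omega_sd
  }
  structure(list(theta = theta, omega_sd = full, sigma_prop = sigma_prop),
            class = "generative_model")
}

.param_names <- c("CL", "Vc", "CLD", "VP", "Ka", "F")

subject_theta <- function(theta, eta) {
  vals <- unlist(theta[.param_names]) * exp(eta)
  as.list(vals)
}

#' Simulate a virtual crossover study
#'
#' Draws bodyweights uniformly from the design range, one eta vector per
#' animal (log-normal parameter variability, shared by both periods), computes
#' the closed-form profiles and perturbs them with proportional residual
#' error, `y = f (1 + eps)`. Draws producing non-positive concentrations are
#' rejected and redrawn so the table contains no values below the limit of
#' quantification, matching the analysed study. Deterministic given `seed`.
#'
#' Each period contributes one dose row (`EVID = 1`), one pre-dose blank row
#' (`BLANK = 1`, excluded from analysis) and one observation row (`EVID = 0`)
#' per sampling time. `TIME` restarts at 0 at each period's dose. `ROUTE` is
#' 1 for the intravenous bolus and 2 for the intramuscular depot dose.
#'
#' @param design a [study_design()].
#' @param gen a [generative_model()].
#' @param seed integer seed.
#' @return An `event_table` data.frame with columns ID, OCC, TIME, AMT, DV,
#'   EVID, ROUTE, BW, BLANK.
#' @export
generate_study <- function(design = study_design(),
                           gen = generative_model(),
                           seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(gen, "generative_model"))
  with_seed(seed, {
    rows <- vector("list", design$n_subjects)
    etas <- matrix(NA_real_, design$n_subjects, 6,
                   dimnames = list(NULL, .param_names))
    for (i in seq_len(design$n_subjects)) {
      bw <- stats::runif(1, design$bw_range[1], design$bw_range[2])
      eta <- stats::rnorm(6, 0, gen$omega_sd)
      etas[i, ] <- eta
      th_i <- subject_theta(gen$theta, eta)
      # honour the F <= 1 invariant only for the typical value; individual
      # availabilities may exceed 1 under log-normal variability
      dose <- design$dose_per_kg * bw
      occ <- list(list(occ = 1, route = 1L, times = design$iv_times),
                  list(occ = 2, route = 2L, times = design$im_times))
      sub <- lapply(occ, function(o) {
        m <- .micro_vec(th_i$CL, th_i$Vc, th_i$CLD, th_i$VP)
        f <- if (o$route == 1L) drop(.conc_iv_mat(m, dose, o$times))
             else drop(.conc_im_mat(m, th_i$Ka, th_i$F, dose, o$times))
        y <- f * (1 + stats::rnorm(length(f), 0, gen$sigma_prop))
        while (any(y <= 0)) {                # no BLQ/negative by construction
          redo <- y <= 0
          y[redo] <- f[redo] *
            (1 + stats::rnorm(sum(redo), 0, gen$sigma_prop))
        }
        nt <- length(o$times)
        list(ID = rep(i, nt + 2), OCC = rep(o$occ, nt + 2),
             TIME = c(0, 0, o$times),
             AMT = c(0, dose, rep(0, nt)),
             DV = c(0, NA, y),
             EVID = c(0L, 1L, rep(0L, nt)),
             ROUTE = rep(o$route, nt + 2), BW = rep(bw, nt + 2),
             BLANK = c(1L, 0L, rep(0L, nt)))
      })
      rows[[i]] <- sub
    }
    flat <- unlist(rows, recursive = FALSE)
    out <- data.frame(lapply(stats::setNames(nm = names(flat[[1]])),
                             function(cn) unlist(lapply(flat, `[[`, cn))))
    class(out) <- c("event_table", "data.frame")
    attr(out, "eta") <- etas     # generative truth, for calibration checks
    out
  })
}

#' Drop observation rows by index
#'
#' Utility for mimicking studies with missing samples: drops the k-th
#' observation rows (counted over non-blank observation rows, in table order).
#'
#' @param events an `event_table`.
#' @param indices integer indices among the observation rows to drop.
#' @return The reduced `event_table`.
#' @export
drop_observations <- function(events, indices) {
  obs <- which(events$EVID == 0 & events$BLANK == 0)
  stopifnot(all(indices >= 1), all(indices <= length(obs)))
  out <- events[-obs[indices], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate calibration and repeatability sets
#'
#' Emulates the bioanalytical validation layout: `n_sets` independent
#' calibration curves over `levels` (signal = intercept + slope * level with
#' proportional noise) and six-replicate repeatability blocks at the stated
#' repeatability levels.
#'
#' @param levels calibration levels, ppb (default the seven levels 1-1000).
#' @param n_sets number of independent calibration sets (default 4).
#' @param slope,intercept true response line.
#' @param noise_cv proportional noise CV (fraction).
#' @param rep_levels repeatability levels, ppb (default 10, 250, 750).
#' @param n_reps replicate injections per repeatability level (default 6).
#' @param seed integer seed.
#' @return A data.frame with columns `kind` ("calibration"/"repeatability"),
#'   `set` (calibration set or replicate index), `level_ppb`, `signal`.
#' @export
generate_calibration <- function(levels = c(1, 10, 100, 250, 500, 750, 1000),
                                 n_sets = 4, slope = 1000, intercept = 0,
                                 noise_cv = 0.02,
                                 rep_levels = c(10, 250, 750), n_reps = 6,
                                 seed = 1) {
  stopifnot(all(levels > 0), all(rep_levels > 0), noise_cv >= 0)
  with_seed(seed, {
    cal <- expand.grid(set = seq_len(n_sets), level_ppb = levels)
    cal <- cal[order(cal$set, cal$level_ppb), ]
    mu <- intercept + slope * cal$level_ppb
    cal_sig <- mu * (1 + stats::rnorm(nrow(cal), 0, noise_cv))
    rep <- expand.grid(set = seq_len(n_reps), level_ppb = rep_levels)
    rep <- rep[order(rep$level_ppb, rep$set), ]
    mu_r <- intercept + slope * rep$level_ppb
    rep_sig <- mu_r * (1 + stats::rnorm(nrow(rep), 0, noise_cv))
    out <- rbind(
      data.frame(kind = "calibration", set = cal$set,
                 level_ppb = cal$level_ppb, signal = cal_sig),
      data.frame(kind = "repeatability", set = rep$set,
                 level_ppb = rep$level_ppb, signal = rep_sig))
    rownames(out) <- NULL
    out
  })
}

#' Simulate tissue residue concentrations
#'
#' Log-normal samples around stated tissue medians, emulating end-of-study
#' liver/kidney/plasma residue measurements.
#'
#' @param median_by_tissue named vector of medians, ug/g.
#' @param spread log-scale SD (0 gives values identical to the medians).
#' @param n samples per tissue.
#' @param seed integer seed.
#' @return A data.frame with columns `tissue`, `replicate`, `conc_ug_g`.
#' @export
generate_tissue <- function(median_by_tissue = c(plasma = 3.26, kidney = 0.29,
                                                 liver = 0.19),
                            spread = 0.15, n = 4, seed = 1) {
  stopifnot(all(median_by_tissue > 0), spread >= 0, n >= 1)
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(median_by_tissue), function(ts) {
      data.frame(tissue = ts, replicate = seq_len(n),
                 conc_ug_g = median_by_tissue[[ts]] *
                   exp(stats::rnorm(n, 0, spread)))
    }))
    rownames(out) <- NULL
    out
  })
}
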