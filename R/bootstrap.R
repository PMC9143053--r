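# Nonparametric bootstrap: resample subjects with replacement, refit each
# replicate, summarize the parameter distributions as percentile intervals.

# rebuild a pop_model around a fit's own estimates (warm-started refits)
model_from_fit <- function(fit) {
  md <- fit$model
  pop_model(theta_init = as_theta(as.list(fit$theta)),
            estimated_iiv = if (!is.null(md)) md$estimated_iiv
                            else .param_names[fit$est],
            omega_init = fit$omega_sd[.param_names[fit$est]],
            fixed_omega_sd = if (!is.null(md)) md$fixed_omega_sd else 0.15,
            error = if (!is.null(md)) md$error else "proportional",
            sigma_init = c(prop = max(fit$sig[["prop"]], 1e-3),
                           add = max(fit$sig[["add"]], 1e-3)),
            sigma_fixed = if (!is.null(md)) md$sigma_fixed else FALSE,
            covariate = if (!is.null(md)) md$covariate else "none",
            ref_bw = if (!is.null(md)) md$ref_bw else 70)
}

# parameters collected from each replicate fit
.boot_params <- function(fit) {
  c(fit$theta[1:5], F_pct = 100 * unname(fit$theta[["F"]]),
    stats::setNames(100 * fit$omega_sd[.param_names[fit$est]],
                    paste0("IIV_", .param_names[fit$est], "_pct")),
    sigma_prop_pct = 100 * fit$sigma_prop)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits every replicate data set
#' (short-chain SAEM by default, warm-started at the original estimates;
#' `method = "laplace"` is available) and reports 2.5/50/97.5 percentile
#' intervals per parameter. Replicates whose refit fails are excluded and
#' counted; a success rate below 50% flags the result unreliable.
#'
#' @param data the original event table.
#' @param fit the original `pk_fit` (provides the model and starting values);
#'   when NULL the model is fit first with `model`.
#' @param model optional [pop_model()] used when `fit` is NULL.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param method refit method.
#' @param control [fit_control()] overrides for the refits (defaults reduce
#'   the chain length and skip SE/MOFV computation).
#' @param indices optional list of pre-specified subject index vectors, one
#'   per replicate (testing hook; overrides the random resampling).
#' @return List of class `pk_bootstrap`: `table` (percentiles per parameter),
#'   `estimates` (replicate-by-parameter matrix), `success_rate`,
#'   `n_failed`, `original` (point estimates), `reliable`.
#' @export
pk_bootstrap <- function(data, fit = NULL, model = NULL, n_boot = 200,
                         seed = 1, method = c("saem", "laplace"),
                         control = list(), indices = NULL) {
  method <- match.arg(method)
  stopifnot(n_boot >= 1)
  ctl <- utils::modifyList(
    fit_control(n_burn = 60, n_iter = 60, compute_se = FALSE,
                compute_mofv = FALSE),
    control)
  if (is.null(fit))
    fit <- fit_population(data, model, method = method, seed = seed,
                          control = ctl)
  boot_model <- model_from_fit(fit)
  ids <- unique(data$ID)
  N <- length(ids)
  if (N < 2) stop("bootstrap needs at least 2 subjects", call. = FALSE)
  draws <- with_seed(seed + 1L, {
    if (!is.null(indices)) indices
    else lapply(seq_len(n_boot), function(b)
      sample.int(N, N, replace = TRUE))
  })
  est <- list()
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    pick <- draws[[b]]
    res <- lapply(seq_along(pick), function(k) {
      sub <- data[data$ID == ids[pick[k]], , drop = FALSE]
      sub$ID <- k
      sub
    })
    bdata <- do.call(rbind, res)
    bf <- try(fit_population(bdata, boot_model, method = method,
                             seed = seed + 1L + b, control = ctl),
              silent = TRUE)
    if (inherits(bf, "try-error") || bf$status == "failed") {
      n_failed <- n_failed + 1L
      next
    }
    est[[length(est) + 1L]] <- .boot_params(bf)
  }
  if (!length(est))
    stop("all bootstrap refits failed", call. = FALSE)
  E <- do.call(rbind, est)
  tab <- data.frame(
    parameter = colnames(E),
    p2.5 = apply(E, 2, stats::quantile, 0.025),
    p50 = apply(E, 2, stats::quantile, 0.5),
    p97.5 = apply(E, 2, stats::quantile, 0.975))
  rownames(tab) <- NULL
  success <- nrow(E) / n_boot
  if (success < 0.5)
    warning("bootstrap success rate below 50%; result flagged unreliable")
  structure(list(table = tab, estimates = E, success_rate = success,
                 n_failed = n_failed, original = .boot_params(fit),
                 reliable = success >= 0.5),
            class = "pk_bootstrap")
}
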