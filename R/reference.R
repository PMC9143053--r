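#' Published final-model estimates for carprofen in swine
#'
#' The published population estimates from the simultaneous IV + IM crossover
#' analysis of carprofen (4 mg/kg) in Yorkshire-Landrace pigs. These values are
#' used as the default generative truth of the synthetic-study module and as
#' the worked-example inputs of the reporting helpers. Between-animal
#' variabilities are expressed in the usual exponential-model convention,
#' CV% = 100 * sqrt(omega^2); parameters without an estimated variability carry
#' omega^2 = 0.0225 (15% CV).
#'
#' @return A list with components:
#' \describe{
#'   \item{theta}{[theta_fixed()] typical values (CL 0.255 L/h, Vc 7.11 L,
#'     CLD 127 L/h, VP 2.51 L, Ka 0.471 1/h, F 0.908).}
#'   \item{omega_sd}{named log-scale SDs of the estimated between-animal
#'     variabilities (CL, Vc, Ka).}
#'   \item{fixed_omega_sd}{log-scale SD applied to the remaining parameters
#'     (0.15, i.e. omega^2 = 0.0225).}
#'   \item{sigma_prop}{proportional residual SD (0.2423, i.e. 24.23% CV).}
#'   \item{mean_bw}{mean bodyweight of the study animals, kg (31.5).}
#'   \item{rse_pct}{published relative standard errors, for reference only.}
#' }
#' @export
carprofen_reference <- function() {
  list(
    theta = theta_fixed(CL = 0.255, Vc = 7.11, CLD = 127.0, VP = 2.51,
                        Ka = 0.471, F = 0.908),
    omega_sd = c(CL = 0.3317, Vc = 0.3347, Ka = 0.9586),
    fixed_omega_sd = 0.15,
    sigma_prop = 0.2423,
    mean_bw = 31.5,
    rse_pct = c(CL = 20.75, Vc = 25.60, CLD = 21.50, VP = 92.43,
                F = 11.89, Ka = 49.26, IIV_CL = 110, IIV_Vc = 220,
                IIV_Ka = 54, sigma_prop = 21.47)
  )
}
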