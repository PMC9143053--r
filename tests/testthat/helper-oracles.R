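# Independent oracles used by the test suite. The linear compartment system
# is solved here with a matrix exponential (Matrix::expm) over the full
# depot/central/peripheral rate matrix -- numerically exact and entirely
# independent of the package's closed-form implementation.

# 3x3 rate matrix over (depot, central, peripheral) amounts
oracle_rate_matrix <- function(theta) {
  k10 <- theta$CL / theta$Vc
  k12 <- theta$CLD / theta$Vc
  k21 <- theta$CLD / theta$VP
  matrix(c(-theta$Ka, 0, 0,
           theta$Ka, -(k10 + k12), k21,
           0, k12, -k21),
         3, 3, byrow = TRUE)
}

# concentration at `times` after a single dose at t = 0
oracle_conc <- function(theta, dose, route, times) {
  M <- oracle_rate_matrix(theta)
  a0 <- if (route == "iv") c(0, dose, 0) else c(theta$F * dose, 0, 0)
  vapply(times, function(t) {
    a <- as.numeric(Matrix::expm(M * t) %*% a0)
    a[2] / theta$Vc
  }, numeric(1))
}

# multiple doses: piecewise propagation with compartment resets
oracle_conc_multi <- function(theta, events, times) {
  M <- oracle_rate_matrix(theta)
  pts <- sort(unique(c(events$time, times)))
  a <- c(0, 0, 0)
  t_cur <- 0
  conc <- numeric(length(times))
  for (p in pts) {
    if (p > t_cur) {
      a <- as.numeric(Matrix::expm(M * (p - t_cur)) %*% a)
      t_cur <- p
    }
    hit <- which(abs(times - p) < 1e-12)
    if (length(hit)) conc[hit] <- a[2] / theta$Vc
    ev <- which(abs(events$time - p) < 1e-12)
    for (e in ev) {
      if (events$route[e] == "iv") a[2] <- a[2] + events$amount[e]
      else a[1] <- a[1] + theta$F * events$amount[e]
    }
  }
  conc
}

# disposition rates as eigenvalue magnitudes of the 2x2 central/peripheral
# rate matrix
oracle_disposition_rates <- function(theta) {
  k10 <- theta$CL / theta$Vc
  k12 <- theta$CLD / theta$Vc
  k21 <- theta$CLD / theta$VP
  A2 <- matrix(c(-(k10 + k12), k21, k12, -k21), 2, 2, byrow = TRUE)
  sort(abs(eigen(A2, only.values = TRUE)$values), decreasing = TRUE)
}

# random strictly positive parameter sets for property tests
random_theta <- function() {
  theta_fixed(CL = exp(stats::runif(1, log(0.05), log(5))),
              Vc = exp(stats::runif(1, log(1), log(50))),
              CLD = exp(stats::runif(1, log(0.1), log(200))),
              VP = exp(stats::runif(1, log(0.5), log(50))),
              Ka = exp(stats::runif(1, log(0.1), log(5))),
              F = stats::runif(1, 0.3, 1))
}

ref_theta <- function() carprofen_reference()$theta

# coerce a plain parameter list to theta_fixed, clamping F at 1 (log-normal
# subject-level draws may exceed it)
as_theta_list <- function(l)
  theta_fixed(l$CL, l$Vc, l$CLD, l$VP, l$Ka, min(l$F, 1))

# brute-force Mann-Whitney oracle on the raw values: pairwise-win statistic
# and a two-sided doubled-tail p over every assignment of the pooled values
oracle_mw <- function(a, b) {
  u_stat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(a, b)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  u_obs <- u_stat(a, b)
  eps <- 1e-9
  p <- min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
  list(U = u_obs, p = p)
}
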