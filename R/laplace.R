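# Laplace-approximate marginal likelihood: deterministic fallback estimator,
# source of the observed-information standard errors, and host of the
# empirical-Bayes and importance-sampling computations.

# finite-difference Hessian (central differences)
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  hs <- pmax(abs(x), 1) * h
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, hs[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hs[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(d), j, hs[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hs[i] * hs[j])
    }
  }
  H
}

# replicate a subject slice's observation rows to batch size n
.fd_rep <- function(fdk, n) {
  for (r in c("iv", "im")) if (!is.null(fdk[[r]]))
    fdk[[r]]$Y <- fdk[[r]]$Y[rep(1L, n), , drop = FALSE]
  fdk
}

# per-subject joint negative log density toolkit: scalar objective, batched
# (one vectorized likelihood call) gradient and Hessian in eta (phi = m + eta)
.subject_nlp_fns <- function(fdk, m_k, Omega_inv, logdet, sig) {
  force(fdk); force(m_k)
  cache <- new.env(parent = emptyenv())
  batch <- function(E) {
    n <- nrow(E)
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <- .fd_rep(fdk, n)
    phi <- sweep(E, 2, m_k, "+")
    -.ll_rows(phi, cache[[key]], sig) +
      0.5 * rowSums((E %*% Omega_inv) * E) + 0.5 * logdet + 3 * log(2 * pi)
  }
  nlp <- function(eta) batch(matrix(eta, 1))
  gr <- function(eta, h = 1e-5) {
    E <- matrix(eta, 12, 6, byrow = TRUE)
    for (j in 1:6) {
      E[2 * j - 1, j] <- eta[j] + h
      E[2 * j, j] <- eta[j] - h
    }
    v <- batch(E)
    (v[seq(1, 11, 2)] - v[seq(2, 12, 2)]) / (2 * h)
  }
  hess <- function(eta, h = 1e-3) {
    pts <- list()
    for (j in 1:6) {
      for (s in c(h, -h)) {
        e <- numeric(6); e[j] <- s
        pts[[length(pts) + 1L]] <- e
      }
    }
    for (i in 2:6) for (j in seq_len(i - 1)) {
      for (si in c(h, -h)) for (sj in c(h, -h)) {
        e <- numeric(6); e[i] <- si; e[j] <- sj
        pts[[length(pts) + 1L]] <- e
      }
    }
    E <- sweep(do.call(rbind, pts), 2, eta, "+")
    v <- batch(rbind(E, eta))
    f0 <- v[length(v)]
    H <- matrix(0, 6, 6)
    for (j in 1:6)
      H[j, j] <- (v[2 * j - 1] + v[2 * j] - 2 * f0) / h^2
    idx <- 12L
    for (i in 2:6) for (j in seq_len(i - 1)) {
      H[i, j] <- H[j, i] <-
        (v[idx + 1] - v[idx + 2] - v[idx + 3] + v[idx + 4]) / (4 * h^2)
      idx <- idx + 4L
    }
    H
  }
  list(nlp = nlp, gr = gr, hess = hess)
}

# empirical-Bayes modes (and optionally Hessians) for all subjects
compute_ebe <- function(fd, mu, O, Omega, sig, start = NULL, hessians = FALSE) {
  N <- fd$N
  U <- chol(Omega)
  Omega_inv <- chol2inv(U)
  logdet <- 2 * sum(log(diag(U)))
  eta <- matrix(0, N, 6)
  H <- if (hessians) vector("list", N) else NULL
  g2 <- numeric(N)
  for (k in seq_len(N)) {
    fdk <- .fd_subject(fd, k)
    m_k <- mu + O[k, ]
    fns <- .subject_nlp_fns(fdk, m_k, Omega_inv, logdet, sig)
    st <- if (is.null(start)) numeric(6) else start[k, ]
    op <- stats::nlminb(st, fns$nlp, gradient = fns$gr,
                        control = list(iter.max = 200))
    eta[k, ] <- op$par
    g2[k] <- op$objective
    if (hessians) {
      Hk <- fns$hess(op$par)
      ev <- eigen((Hk + t(Hk)) / 2, symmetric = TRUE)
      ev$values <- pmax(ev$values, 1e-8)
      H[[k]] <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
    }
  }
  list(eta = eta, nlp_min = g2, hessians = H)
}

# Laplace -2 log marginal likelihood of the whole data set
laplace_m2ll <- function(fd, mu, O, Omega, sig, start = NULL) {
  eb <- compute_ebe(fd, mu, O, Omega, sig, start = start, hessians = TRUE)
  m2 <- 0
  for (k in seq_len(fd$N)) {
    ld <- determinant(eb$hessians[[k]], logarithm = TRUE)$modulus
    m2 <- m2 + 2 * eb$nlp_min[k] - 6 * log(2 * pi) + ld
  }
  attr(m2, "eta") <- eb$eta
  m2
}

# pack/unpack the estimated transformed parameters into a single vector
make_packer <- function(model, held, est) {
  sig_free <- if (model$sigma_fixed) character(0)
  else switch(model$error, proportional = "prop", additive = "add",
              combined = c("add", "prop"))
  mu_free <- setdiff(seq_len(6), held)
  est_expo <- model$covariate == "allometric_estimated"
  list(
    mu_free = mu_free, sig_free = sig_free, est = est, est_expo = est_expo,
    n_params = length(mu_free) + length(est) + length(sig_free) +
      if (est_expo) 2L else 0L,
    pack = function(mu, Omega, sig, expo) {
      c(mu[mu_free], log(sqrt(diag(Omega)[est])),
        if (length(sig_free)) log(sig[sig_free]),
        if (est_expo) expo)
    },
    unpack = function(p, mu0, Omega0, sig0, expo0) {
      i <- 0
      mu <- mu0; mu[mu_free] <- p[seq_along(mu_free)]
      i <- length(mu_free)
      Omega <- Omega0
      if (length(est)) {
        diag(Omega)[est] <- exp(2 * p[i + seq_along(est)])
        i <- i + length(est)
      }
      sig <- sig0
      if (length(sig_free)) {
        sig[sig_free] <- exp(p[i + seq_along(sig_free)])
        i <- i + length(sig_free)
      }
      expo <- expo0
      if (est_expo) expo <- p[i + 1:2]
      list(mu = mu, Omega = Omega, sig = sig, expo = expo)
    })
}

laplace_engine <- function(fd, model, seed, control) {
  ctl <- utils::modifyList(fit_control(), control)
  N <- fd$N
  x <- if (model$covariate == "none" || all(is.na(fd$bw))) rep(0, N)
       else log(fd$bw / model$ref_bw)
  expo0 <- switch(model$covariate, none = c(0, 0),
                  allometric_fixed = c(0.75, 1),
                  allometric_estimated = c(0.75, 1))
  held <- .held_components(fd)
  if (length(held))
    warning("only one route in the data; holding ",
            paste(.param_names[held], collapse = ", "), " at initial values")
  est <- setdiff(model$est_idx, held)
  if (model$full_block)
    stop("full_block covariance requires method = 'saem'", call. = FALSE)
  mu0 <- phi_from_theta(model$theta_init)
  Omega0 <- diag(model$omega_sd_init^2)
  sig0 <- .sigma_pack(model)
  pk <- make_packer(model, held, est)
  cache <- new.env(parent = emptyenv())
  cache$eta <- matrix(0, N, 6)
  obj <- function(p) {
    u <- pk$unpack(p, mu0, Omega0, sig0, expo0)
    O <- .cov_offsets(x, u$expo)
    v <- try(laplace_m2ll(fd, u$mu, O, u$Omega, u$sig, start = cache$eta),
             silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(1e10)
    cache$eta <- attr(v, "eta")
    as.numeric(v)
  }
  lo <- rep(-Inf, pk$n_params)
  sd_floor <- c(rep(-Inf, length(pk$mu_free)),
                rep(log(ctl$omega_min_sd), length(est)),
                rep(log(ctl$sigma_min), length(pk$sig_free)),
                if (pk$est_expo) c(-Inf, -Inf))
  lo <- pmax(lo, sd_floor, na.rm = TRUE)
  hi <- rep(Inf, pk$n_params)
  if (6L %in% pk$mu_free)                       # keep F off the boundary
    hi[match(6L, pk$mu_free)] <- stats::qlogis(0.999)
  op <- stats::nlminb(pk$pack(mu0, Omega0, sig0, expo0), obj, lower = lo,
                      upper = hi,
                      control = list(iter.max = ctl$laplace_maxit,
                                     rel.tol = 1e-8))
  u <- pk$unpack(op$par, mu0, Omega0, sig0, expo0)
  list(mu = u$mu, Omega = u$Omega, sig = u$sig, expo = u$expo, x = x,
       O = .cov_offsets(x, u$expo), est = est, held = held,
       trace = NULL, objective = op$objective,
       status_code = op$convergence, n_iter_run = op$iterations,
       phi_last = matrix(u$mu, N, 6, byrow = TRUE) + .cov_offsets(x, u$expo) +
         cache$eta)
}

# log density of the multivariate t proposal used by importance sampling
.lmvt <- function(Z_maha, logdet_S, d = 6, df = 4) {
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    0.5 * logdet_S - ((df + d) / 2) * log1p(Z_maha / df)
}

# -2 marginal log-likelihood by importance sampling at fixed estimates
importance_m2ll <- function(fd, mu, O, Omega, sig, seed, n_samples = 1000,
                            df = 4, eb = NULL) {
  if (is.null(eb)) eb <- compute_ebe(fd, mu, O, Omega, sig, hessians = TRUE)
  U <- chol(Omega)
  Omega_inv <- chol2inv(U)
  logdetO <- 2 * sum(log(diag(U)))
  with_seed(seed, {
    total <- 0
    for (k in seq_len(fd$N)) {
      S <- chol2inv(chol(eb$hessians[[k]]))   # proposal scale = inv Hessian
      Us <- chol((S + t(S)) / 2)
      logdetS <- 2 * sum(log(diag(Us)))
      Z <- matrix(stats::rnorm(n_samples * 6), n_samples, 6)
      w_chi <- stats::rchisq(n_samples, df) / df
      D <- (Z / sqrt(w_chi)) %*% Us
      eta_s <- sweep(D, 2, eb$eta[k, ], "+")
      maha <- rowSums((D %*% chol2inv(Us)) * D)
      lq <- .lmvt(maha, logdetS, df = df)
      fdk <- .fd_subject(fd, k)
      # replicate the observation rows so the vectorized likelihood aligns
      # one draw per row
      for (r in c("iv", "im")) if (!is.null(fdk[[r]]))
        fdk[[r]]$Y <- fdk[[r]]$Y[rep(1L, n_samples), , drop = FALSE]
      phi_s <- sweep(eta_s, 2, mu + O[k, ], "+")
      ll <- .ll_rows(phi_s, fdk, sig)
      lp <- -0.5 * rowSums((eta_s %*% Omega_inv) * eta_s) -
        0.5 * logdetO - 3 * log(2 * pi)
      w <- ll + lp - lq
      mx <- max(w)
      total <- total + (mx + log(mean(exp(w - mx))))
    }
    -2 * total
  })
}
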