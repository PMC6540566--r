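# shared fixture builders and numerical-derivative oracles

make_data <- function(k, delta, Z = NULL, r = max(k)) {
  ph <- tibble::tibble(sample_id = paste0("s", seq_along(k)),
                       interval = k, event = delta)
  cv <- NULL
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    colnames(Z) <- paste0("z", seq_len(ncol(Z)))
    cv <- dplyr::bind_cols(tibble::tibble(sample_id = ph$sample_id),
                           tibble::as_tibble(Z))
  }
  grouped_data(ph, cv, r = r)
}

# random interior-point instance: every interval gets at least one event
rand_instance <- function(n, r, q, seed) {
  set.seed(seed)
  k <- c(seq_len(r), sample.int(r, n - r, replace = TRUE))
  delta <- c(rep(1L, r), rbinom(n - r, 1, 0.6))
  Z <- if (q) matrix(rnorm(n * q), n, q) else NULL
  x <- rnorm(n)
  alpha <- runif(r, 0.4, 0.9)
  theta <- if (q) runif(q, -0.5, 0.5) else numeric(0)
  list(data = make_data(k, delta, Z, r = r), x = x, alpha = alpha,
       theta = theta, beta = runif(1, -0.5, 0.5))
}

# central finite-difference gradient of f at x
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 1.0)
}

# finite-difference Hessian (via gradient of the FD gradient)
fd_hess <- function(f, x, h = 1e-5) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    e <- rep(0, d); e[i] <- h
    H[i, ] <- (fd_grad(f, x + e, h) - fd_grad(f, x - e, h)) / (2 * h)
  }
  (H + t(H)) / 2
}

# log-likelihood as a function of (beta, theta, zeta[est]), holding the
# remaining alphas at the null-fit values; used as an independent oracle
# for the efficient score statistic assembly
restricted_ll <- function(data, x, fit) {
  est <- fit$est
  q <- fit$q
  function(par) {
    alpha <- ifelse(is.na(fit$alpha_hat), 1, pmax(fit$alpha_hat, 1e-12))
    alpha[est] <- exp(-exp(par[1 + q + seq_along(est)]))
    grouped_loglik(data, x = x, beta = par[1],
                   theta = par[1 + seq_len(q)], alpha = alpha)
  }
}

# Eq.-style efficient score statistic computed entirely from finite
# differences of the restricted log-likelihood (independent of the
# analytic engine)
fd_efficient_W <- function(data, x, fit) {
  f <- restricted_ll(data, x, fit)
  par0 <- c(0, fit$theta_hat, log(-log(fit$alpha_hat[fit$est])))
  g <- fd_grad(f, par0)
  I <- -fd_hess(f, par0)
  Ibb <- I[1, 1]
  Ibn <- I[1, -1, drop = FALSE]
  Inn <- I[-1, -1, drop = FALSE]
  drop(g[1]^2 / (Ibb - Ibn %*% solve(Inn, t(Ibn))))
}

sim_fixture <- function(n = 200, beta = 0, maf = 0.3, seed = 1,
                        c_max = 2.5, ...) {
  cfg <- sim_config(n = n, beta = beta, maf = maf, c_max = c_max,
                    seed = seed, ...)
  simulate_grouped(cfg)
}
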