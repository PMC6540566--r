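# Core likelihood / score / information engine for the grouped
# failure-time proportional-hazards model.
#
# Per-sample likelihood:
#   L_i = (1 - alpha_{k_i}^{w_i})^{delta_i} * prod_{j < k_i} alpha_j^{w_i},
#   w_i = exp(x_i beta + z_i' theta),
# with alpha_j in (0, 1] the baseline probability of surviving interval j.
# Internally the nuisance block is parameterized as zeta_j = log(-log alpha_j)
# (complementary log-log scale, unconstrained); a_j = log alpha_j = -exp(zeta_j).
#
# With u_i = w_i * a_{k_i} (<= 0) the event factor is f(u) = log(1 - e^u),
# f'(u)  = -e^u / (1 - e^u) = -1/expm1(-u),
# f''(u) = -e^u / (1 - e^u)^2 = -f'(u)^2 * e^{-u}.
# Both du/d(nu) and du/d(zeta_{k_i}) equal u, and the second derivative of u
# with respect to any pair among {nu, zeta_{k_i}} is again u, so the event
# term contributes f'(u) u to each first derivative and f''(u) u^2 + f'(u) u
# to each second derivative involving nu and/or zeta_{k_i}.  The survival
# terms w_i a_j (j < k_i) are linear in each a_j, giving the per-interval
# sums below; the zeta-zeta block is therefore diagonal.

gs_linpred <- function(n, X, beta, Z, theta) {
  nu <- numeric(n)
  if (!is.null(X) && length(beta)) nu <- nu + drop(X %*% beta)
  if (!is.null(Z) && ncol(Z) && length(theta)) nu <- nu + drop(Z %*% theta)
  nu
}

# sum v by interval index k into a length-r vector (intervals never hit -> 0)
gs_bink <- function(v, k, r) {
  out <- numeric(r)
  rs <- rowsum(v, k, reorder = TRUE)
  out[as.integer(rownames(rs))] <- rs
  out
}

gs_bink_mat <- function(M, k, r) {
  out <- matrix(0, r, ncol(M))
  rs <- rowsum(M, k, reorder = TRUE)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# total log-likelihood; a = log alpha (length r, entries <= 0)
gs_loglik <- function(k, delta, Z, X, beta, theta, a) {
  n <- length(k)
  nu <- gs_linpred(n, X, beta, Z, theta)
  w <- exp(nu)
  csA <- cumsum(c(0, a))
  ll <- sum(w * csA[k])
  ev <- which(delta == 1L)
  if (length(ev)) {
    u <- w[ev] * a[k[ev]]
    ll <- ll + sum(log(-expm1(u))) # log(1 - alpha^w); -Inf if alpha = 1
  }
  ll
}

# Analytic gradient and Hessian of the total log-likelihood with respect to
# (beta, theta, zeta[est]).  X may be NULL (null model), a matrix n x p
# otherwise.  `est` indexes the intervals whose zeta is free; all other
# entries of `a` are held fixed.  delta must already have events in
# boundary (alpha = 0) intervals zeroed out.
gs_score_hess <- function(k, delta, Z, X, beta, theta, a, est,
                          per_sample = FALSE) {
  n <- length(k)
  q <- ncol(Z)
  p <- if (is.null(X)) 0L else ncol(X)
  r <- length(a)
  ne <- length(est)

  nu <- gs_linpred(n, X, beta, Z, theta)
  w <- exp(nu)
  csA <- cumsum(c(0, a))
  wA <- w * csA[k]

  evs <- numeric(n)   # event first-derivative factor f'(u) u
  qv <- numeric(n)    # event second-derivative factor f''(u) u^2 + f'(u) u
  ev <- which(delta == 1L)
  if (length(ev)) {
    u <- w[ev] * a[k[ev]]
    h <- -1 / expm1(-u)
    fpp <- -h * h * exp(-u)
    evs[ev] <- h * u
    qv[ev] <- fpp * u * u + h * u
  }
  snu <- evs + wA   # d l_i / d nu_i
  Hnn <- qv + wA    # d^2 l_i / d nu_i^2

  # per-interval sums for the zeta block
  rw <- gs_bink(w, k, r)
  wgt <- sum(rw) - cumsum(rw)         # sum of w_i over samples with k_i > j
  Evk <- gs_bink(evs, k, r)
  Qsk <- gs_bink(qv, k, r)
  g_z <- (a * wgt + Evk)[est]
  h_zz <- (a * wgt + Qsk)[est]

  if (q) {
    g_t <- drop(crossprod(Z, snu))
    H_tt <- crossprod(Z, Z * Hnn)
    ZW <- gs_bink_mat(Z * w, k, r)
    ZWgt <- rep(colSums(ZW), each = r) - apply(ZW, 2, cumsum)
    ZQ <- gs_bink_mat(Z * qv, k, r)
    H_tz <- t((ZWgt * a + ZQ)[est, , drop = FALSE])  # q x ne
  } else {
    g_t <- numeric(0)
    H_tt <- matrix(0, 0, 0)
    H_tz <- matrix(0, 0, ne)
  }

  if (p) {
    g_b <- drop(crossprod(X, snu))
    H_bb <- crossprod(X, X * Hnn)
    H_bt <- crossprod(X, Z * Hnn)
    XW <- gs_bink_mat(X * w, k, r)
    XWgt <- rep(colSums(XW), each = r) - apply(XW, 2, cumsum)
    XQ <- gs_bink_mat(X * qv, k, r)
    H_bz <- t((XWgt * a + XQ)[est, , drop = FALSE])  # p x ne
  } else {
    g_b <- numeric(0)
    H_bb <- matrix(0, 0, 0)
    H_bt <- matrix(0, 0, q)
    H_bz <- matrix(0, 0, ne)
  }

  d <- p + q + ne
  H <- matrix(0, d, d)
  ib <- seq_len(p)
  it <- p + seq_len(q)
  iz <- p + q + seq_len(ne)
  if (p) {
    H[ib, ib] <- H_bb
    if (q) { H[ib, it] <- H_bt; H[it, ib] <- t(H_bt) }
    H[ib, iz] <- H_bz; H[iz, ib] <- t(H_bz)
  }
  if (q) {
    H[it, it] <- H_tt
    H[it, iz] <- H_tz; H[iz, it] <- t(H_tz)
  }
  if (ne) H[cbind(iz, iz)] <- h_zz

  out <- list(score = unname(c(g_b, g_t, g_z)), hess = H,
              snu = snu, Hnn = Hnn, w = w, n = n, p = p, q = q, est = est)

  if (per_sample) {
    # n x ne per-sample score and Hessian-diagonal structure for zeta
    ind <- outer(k, est, ">")
    Sz <- (w %o% a[est]) * ind
    Hz <- Sz
    if (length(ev)) {
      pos <- match(k[ev], est)
      ok <- which(!is.na(pos))
      if (length(ok)) {
        at <- cbind(ev[ok], pos[ok])
        Sz[at] <- Sz[at] + evs[ev[ok]]
        Hz[at] <- Hz[at] + qv[ev[ok]]
      }
    }
    out$Sz <- Sz
    out$Hz <- Hz
    ps <- cbind(if (p) X * snu, if (q) Z * snu, Sz)
    dimnames(ps) <- NULL
    out$per_sample <- ps
  }
  out
}

check_alpha <- function(alpha, r) {
  if (!is.numeric(alpha) || length(alpha) != r) {
    stop("`alpha` must be a numeric vector of length r = ", r)
  }
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha > 1)) {
    stop("alpha_j must lie in (0, 1]")
  }
  invisible(alpha)
}

check_x <- function(x, n) {
  if (is.null(x)) return(NULL)
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(X) != n) stop("`x` must have one value per sample")
  if (any(!is.finite(X))) stop("`x` must be finite (drop missing values first)")
  X
}

#' Grouped-model log-likelihood
#'
#' Evaluates the total log-likelihood of the grouped failure-time
#' proportional-hazards model, `sum_i delta_i log(1 - alpha_{k_i}^{w_i}) +
#' w_i sum_{j < k_i} log alpha_j` with `w_i = exp(x_i beta + z_i' theta)`,
#' using numerically safe `expm1`/`log1p` forms. An event in an interval
#' with `alpha_j = 1` yields `-Inf` (an impossible event under the model),
#' returned as a value rather than an error.
#'
#' @param data A [grouped_data()] object.
#' @param x Optional variable of interest (numeric vector of length n, or an
#'   n x p matrix).
#' @param beta Effect(s) of `x`; ignored when `x` is `NULL`.
#' @param theta Covariate effects (length `ncol(data$Z)`).
#' @param alpha Baseline interval survival probabilities, length `r`,
#'   each in (0, 1].
#' @return The scalar total log-likelihood (each per-sample term is <= 0).
#' @export
grouped_loglik <- function(data, x = NULL, beta = 0, theta = numeric(0), alpha) {
  stop_not_grouped(data)
  check_alpha(alpha, data$r)
  X <- check_x(x, data$n)
  if (length(theta) != ncol(data$Z)) {
    stop("`theta` must have length ", ncol(data$Z))
  }
  if (!is.null(X) && length(beta) != ncol(X)) stop("length(beta) != ncol(x)")
  if (any(!is.finite(beta)) || (length(theta) && any(!is.finite(theta)))) {
    stop("parameters must be finite")
  }
  gs_loglik(data$k, data$delta, data$Z, X, beta, theta, log(alpha))
}

#' Score vector and averaged information blocks
#'
#' Analytic first derivatives of the grouped-model log-likelihood with
#' respect to `(beta, theta, zeta)` — where `zeta_j = log(-log alpha_j)` is
#' the unconstrained complementary-log-log transform of the interval
#' survival probabilities — together with the averaged observed information
#' (negative Hessian of the mean log-likelihood) partitioned into the
#' `beta`-block, the `beta`-nuisance block and the nuisance block.
#'
#' @inheritParams grouped_loglik
#' @param x Variable of interest, vector or n x p matrix (required here).
#' @return A list (the score bundle) with elements `score` (length
#'   `p + q + r`, ordered beta, theta, zeta-block), `per_sample_scores`
#'   (n x (p+q+r)), `info_bb`, `info_bn`, `info_nn` (averaged information
#'   blocks) and `n`. `score` equals the column sums of
#'   `per_sample_scores`, and `info_nn` is symmetric.
#' @export
grouped_score <- function(data, x, beta = 0, theta = numeric(0), alpha) {
  stop_not_grouped(data)
  check_alpha(alpha, data$r)
  if (any(data$delta == 1L & alpha[data$k] >= 1)) {
    stop("alpha_j must be strictly < 1 for intervals containing events")
  }
  X <- check_x(x, data$n)
  if (is.null(X)) stop("`x` is required")
  if (length(theta) != ncol(data$Z)) stop("`theta` must have length ", ncol(data$Z))
  if (length(beta) != ncol(X)) stop("length(beta) != ncol(x)")
  if (any(alpha >= 1)) {
    stop("grouped_score() reports the full zeta block; alpha_j = 1 is not ",
         "representable on the zeta scale (fit_null() handles such intervals)")
  }
  eng <- gs_score_hess(data$k, data$delta, data$Z, X, beta, theta,
                       log(alpha), seq_len(data$r), per_sample = TRUE)
  p <- eng$p; q <- eng$q; r <- data$r; n <- data$n
  I <- -eng$hess / n
  ib <- seq_len(p); inn <- p + seq_len(q + r)
  list(score = eng$score,
       per_sample_scores = eng$per_sample,
       info_bb = if (p == 1) I[ib, ib] else I[ib, ib, drop = FALSE],
       info_bn = I[ib, inn, drop = FALSE],
       info_nn = I[inn, inn, drop = FALSE],
       n = n)
}
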