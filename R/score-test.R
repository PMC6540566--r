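# Per-variant efficient score machinery.
#
# All quantities are evaluated at (beta = 0, eta-hat), the null MLE of the
# nuisance parameters.  Because the zeta-zeta Hessian block is diagonal and
# every block factorizes into per-sample pieces, the null fit is cached once
# (null_cache) and each variant costs O(n (q + r)).

# Cache per-sample pieces of the score and information at the null MLE.
null_cache <- function(data, fit) {
  sub <- gs_subset(data, fit$idx)
  eng <- gs_score_hess(sub$k, fit$delta_eff, sub$Z, NULL, numeric(0),
                       fit$theta_hat, fit$a, fit$est, per_sample = TRUE)
  q <- fit$q; ne <- length(fit$est)
  S_eta <- cbind(if (q) sub$Z * eng$snu, eng$Sz)     # n x (q+ne)
  I_nn <- -rbind(
    cbind(if (q) crossprod(sub$Z, sub$Z * eng$Hnn) else matrix(0, 0, 0),
          if (q) crossprod(sub$Z, eng$Hz) else matrix(0, 0, ne)),
    cbind(if (q) t(crossprod(sub$Z, eng$Hz)) else matrix(0, ne, 0),
          diag(colSums(eng$Hz), ne))
  )
  list(sub = sub, snu = eng$snu, Hnn = eng$Hnn, Hz = eng$Hz,
       S_eta = S_eta, I_nn = I_nn, q = q, ne = ne)
}

# information blocks on a row subset `ok` of the cache
eta_info_subset <- function(cache, ok) {
  Z <- cache$sub$Z[ok, , drop = FALSE]
  Hnn <- cache$Hnn[ok]
  Hz <- cache$Hz[ok, , drop = FALSE]
  q <- cache$q; ne <- cache$ne
  -rbind(
    cbind(if (q) crossprod(Z, Z * Hnn) else matrix(0, 0, 0),
          if (q) crossprod(Z, Hz) else matrix(0, 0, ne)),
    cbind(if (q) t(crossprod(Z, Hz)) else matrix(0, ne, 0),
          diag(colSums(Hz), ne))
  )
}

#' Efficient score test for one variable of interest
#'
#' Tests `H0: beta = 0` for the variable `x` under the grouped
#' failure-time model, treating the covariate effects and the interval
#' survival probabilities as nuisance parameters estimated once under the
#' null. The statistic is the squared total score for `beta` divided by
#' the efficient information — the `beta` information minus its projection
#' onto the nuisance directions — and is asymptotically chi-square with
#' `ncol(x)` degrees of freedom. The analysis is complete-case in `x`:
#' samples with a missing value are removed from the score sums and the
#' information blocks (the global null MLE is retained).
#'
#' @param data A [grouped_data()] object.
#' @param x Variable of interest over the full dataset: numeric vector (or
#'   n x p matrix for a joint p-degree-of-freedom test); `NA` allowed.
#' @param fit A converged [fit_null()] result for `data`.
#' @param cache Optional precomputed cache (used internally by
#'   [scan_variants()]); leave `NULL`.
#' @return A list with `stat` (the statistic, >= 0), `pvalue` (upper-tail
#'   chi-square), `df`, `n` (complete cases used), `score` (total score
#'   for beta), `contributions` (per-sample efficient scores
#'   `u_i = S_beta,i - I_bn I_nn^{-1} S_eta,i` over the complete cases,
#'   `NA` elsewhere, aligned to `fit$fitted_on`), and `status` (`"ok"`,
#'   `"monomorphic"`, or `"boundary"` when a singular nuisance information
#'   forced a pseudo-inverse).
#' @export
efficient_score_test <- function(data, x, fit, cache = NULL) {
  stop_not_grouped(data)
  if (!inherits(fit, "grouped_null_fit")) stop("`fit` must come from fit_null()")
  if (!fit$converged) stop("null fit did not converge")
  if (is.null(cache)) cache <- null_cache(data, fit)

  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(X) != data$n) stop("`x` must have one value per sample in `data`")
  X <- X[fit$idx, , drop = FALSE]
  p <- ncol(X)
  ok <- stats::complete.cases(X)
  n_cc <- sum(ok)
  empty <- list(stat = NA_real_, pvalue = NA_real_, df = p, n = n_cc,
                score = NA_real_, contributions = NULL, status = "monomorphic")
  if (n_cc < 2) return(empty)

  Xc <- X[ok, , drop = FALSE]
  if (all(apply(Xc, 2, function(v) diff(range(v)) == 0))) return(empty)

  status <- "ok"
  snu <- cache$snu[ok]
  S_b <- drop(crossprod(Xc, snu))                       # p
  I_bb <- crossprod(Xc, Xc * cache$Hnn[ok]) * -1        # p x p
  I_bn <- -cbind(crossprod(Xc, cache$sub$Z[ok, , drop = FALSE] * cache$Hnn[ok]),
                 crossprod(Xc, cache$Hz[ok, , drop = FALSE]))
  I_nn <- if (all(ok)) cache$I_nn else eta_info_subset(cache, ok)

  sol <- tryCatch(solve(I_nn, t(I_bn)), error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular nuisance information; using pseudo-inverse")
    status <- "boundary"
    sol <- gs_pinv(I_nn) %*% t(I_bn)
  }
  I_eff <- I_bb - I_bn %*% sol                          # p x p (total scale)
  if (max(abs(I_eff)) <= 1e-10 * max(abs(I_bb), 1e-300)) {
    empty$status <- "monomorphic"
    return(empty)
  }

  W <- tryCatch(drop(crossprod(S_b, solve(I_eff, S_b))),
                error = function(e) NA_real_)
  if (!is.finite(W) || W < 0) {
    empty$status <- "failed"
    return(empty)
  }
  u <- NULL
  if (p == 1) {
    u <- rep(NA_real_, length(cache$snu))
    u[ok] <- drop(Xc) * snu - drop(cache$S_eta[ok, , drop = FALSE] %*% sol)
  }
  list(stat = W, pvalue = stats::pchisq(W, df = p, lower.tail = FALSE),
       df = p, n = n_cc, score = S_b, contributions = u, status = status)
}

#' Maximum likelihood estimate of a variant effect
#'
#' Joint Newton maximization of the grouped-model log-likelihood over
#' `(beta, theta, zeta)`, initialized at `(0, eta-hat)` from the null fit,
#' with step-halving. The standard error comes from the inverse observed
#' information at the optimum. Complete-case in `x`.
#'
#' @inheritParams efficient_score_test
#' @param tol Convergence tolerance on the max-norm of the score.
#' @param max_iter,max_halvings Newton iteration limits.
#' @return A list of class `grouped_beta_fit`: `beta_hat`, `se`,
#'   `converged`, `n_iter`, `loglik`, `n`, `status` (`"ok"`, or `"failed"`
#'   when the estimate diverges or its curvature-based standard error is
#'   meaningless, as under complete separation).
#' @export
estimate_beta <- function(data, x, fit, tol = 1e-8, max_iter = 100L,
                          max_halvings = 20L) {
  stop_not_grouped(data)
  if (!inherits(fit, "grouped_null_fit")) stop("`fit` must come from fit_null()")
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(X) != data$n) stop("`x` must have one value per sample in `data`")
  X <- X[fit$idx, , drop = FALSE]
  ok <- stats::complete.cases(X)
  sub <- gs_subset(gs_subset(data, fit$idx), which(ok))
  delta_eff <- fit$delta_eff[ok]
  Xc <- X[ok, , drop = FALSE]
  p <- ncol(Xc); q <- fit$q; est <- fit$est
  out_failed <- list(beta_hat = NA_real_, se = NA_real_, converged = FALSE,
                     n_iter = 0L, loglik = NA_real_, n = sum(ok),
                     status = "failed")
  class(out_failed) <- "grouped_beta_fit"
  if (sum(ok) < 2 || all(apply(Xc, 2, function(v) diff(range(v)) == 0))) {
    return(out_failed)
  }

  beta <- numeric(p)
  theta <- fit$theta_hat
  a <- fit$a
  ll <- gs_loglik(sub$k, delta_eff, sub$Z, Xc, beta, theta, a)
  converged <- FALSE; iter <- 0L; grad_norm <- Inf
  repeat {
    eng <- gs_score_hess(sub$k, delta_eff, sub$Z, Xc, beta, theta, a, est)
    grad_norm <- max(abs(eng$score))
    if (grad_norm <= tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    step <- tryCatch(drop(solve(eng$hess, eng$score)),
                     error = function(e) drop(gs_pinv(eng$hess) %*% eng$score))
    lam <- 1; improved <- FALSE
    for (h in seq_len(max_halvings + 1L)) {
      beta_c <- beta - lam * step[seq_len(p)]
      th_c <- theta - lam * step[p + seq_len(q)]
      a_c <- a
      a_c[est] <- -exp(log(-a[est]) - lam * step[p + q + seq_along(est)])
      ll_c <- gs_loglik(sub$k, delta_eff, sub$Z, Xc, beta_c, th_c, a_c)
      if (is.finite(ll_c) && ll_c >= ll - 1e-12) {
        beta <- beta_c; theta <- th_c; a <- a_c; ll <- ll_c
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
    if (any(abs(beta) > 50)) {
      out_failed$n_iter <- iter
      return(out_failed)   # separation: likelihood maximized at infinity
    }
  }

  eng <- gs_score_hess(sub$k, delta_eff, sub$Z, Xc, beta, theta, a, est)
  vb <- tryCatch(solve(-eng$hess)[seq_len(p), seq_len(p)],
                 error = function(e) NA_real_)
  se <- suppressWarnings(sqrt(diag(as.matrix(vb))))
  # a flat likelihood (separation) converges in gradient long before the
  # estimate runs away: an absurd curvature-based SE is the reliable sign
  if (any(abs(beta) > 50) || any(!is.finite(se)) || any(se > 100)) {
    out_failed$n_iter <- iter
    return(out_failed)
  }
  alpha_hat <- fit$alpha_hat
  alpha_hat[est] <- exp(a[est])
  structure(list(beta_hat = if (p == 1) beta else unname(beta),
                 se = if (p == 1) se[1] else se,
                 theta_hat = theta,
                 alpha_hat = alpha_hat,
                 converged = converged, n_iter = iter,
                 grad_norm = grad_norm,
                 loglik = ll, n = sum(ok), status = "ok"),
            class = "grouped_beta_fit")
}

#' @export
print.grouped_beta_fit <- function(x, ...) {
  cat("<grouped_beta_fit> beta_hat = ", format(x$beta_hat, digits = 4),
      " (se ", format(x$se, digits = 3), "), n = ", x$n,
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.grouped_beta_fit <- function(x, ...) {
  tibble::tibble(term = "beta", estimate = x$beta_hat, std.error = x$se,
                 statistic = x$beta_hat / x$se,
                 p.value = 2 * stats::pnorm(-abs(x$beta_hat / x$se)))
}

#' @export
glance.grouped_beta_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, n_iter = x$n_iter,
                 converged = x$converged, status = x$status)
}
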