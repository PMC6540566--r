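#' Life-table estimator of the interval survival probabilities
#'
#' Closed-form actuarial estimator `alpha_j = 1 - d_j / (d_j + s_j)`, where
#' `d_j` counts events in interval j and `s_j` counts samples still at risk
#' beyond it (interval index larger than j). This is the exact maximum
#' likelihood estimate of the grouped model without covariates, and the
#' initialization of [fit_null()]. Covariates, if present, are ignored.
#'
#' @param data A [grouped_data()] object.
#' @return A tibble with one row per interval: `interval`, `d` (events),
#'   `s` (survivors beyond), `at_risk`, `alpha` and a `class` column:
#'   `"estimable"` (0 < alpha < 1), `"fixed_one"` (no events, positive at
#'   risk), `"boundary_zero"` (events but no survivors, alpha = 0) or
#'   `"undefined"` (nobody at risk; `alpha` is `NA` and a flag attribute
#'   `any_undefined` is set).
#' @export
life_table_alpha <- function(data) {
  stop_not_grouped(data)
  r <- data$r
  d <- tabulate(data$k[data$delta == 1L], nbins = r)
  beyond <- tabulate(data$k, nbins = r)
  s <- rev(cumsum(rev(beyond))) - beyond     # samples with k > j
  at_risk <- d + s
  alpha <- ifelse(at_risk > 0, 1 - d / pmax(at_risk, 1), NA_real_)
  cls <- dplyr::case_when(
    at_risk == 0 ~ "undefined",
    d == 0 ~ "fixed_one",
    s == 0 ~ "boundary_zero",
    TRUE ~ "estimable"
  )
  out <- tibble::tibble(interval = seq_len(r), d = d, s = s,
                        at_risk = at_risk, alpha = alpha, class = cls)
  attr(out, "any_undefined") <- any(cls == "undefined")
  if (!any(cls == "estimable")) {
    attr(out, "empty_estimable") <- TRUE
    warning("no interval has both events and survivors; ",
            "estimable set is empty")
  } else {
    attr(out, "empty_estimable") <- FALSE
  }
  out
}

#' Null-model maximum likelihood fit of the nuisance parameters
#'
#' Maximizes the grouped-model log-likelihood under the null hypothesis
#' that the variable of interest has no effect (`beta = 0`), jointly over
#' the covariate effects `theta` and the interval survival probabilities
#' `alpha` (optimized on the unconstrained `zeta = log(-log alpha)` scale).
#' The fit is computed once per dataset and reused by every variant test.
#'
#' Newton iterations with step-halving guarantee a non-decreasing
#' log-likelihood path. Intervals with no events but samples at risk are
#' fixed at `alpha = 1` (their life-table value) with a warning; intervals
#' with events but no survivors sit on the `alpha = 0` boundary and their
#' event terms contribute a likelihood factor of exactly 1. Samples with
#' missing covariates are excluded (with a message reporting the count).
#'
#' @param data A [grouped_data()] object with at least one event.
#' @param tol Convergence tolerance on the max-norm of the score vector.
#' @param max_iter Maximum Newton iterations.
#' @param max_halvings Maximum step-halvings within one iteration.
#' @param drop_uninformative Drop `(k = 1, event = 0)` samples (censored at
#'   time 0) from the fitted set entirely instead of carrying them as
#'   zero-contribution rows. Default keeps them, so they still count
#'   toward the sample size used to average the information.
#' @param trace Record the log-likelihood after each iteration.
#' @return An object of class `grouped_null_fit` with elements
#'   `alpha_hat` (length r; 1 for event-free intervals, 0 at the boundary,
#'   `NA` where undefined), `theta_hat`, `converged`, `n_iter`,
#'   `grad_norm`, `loglik`, `fitted_on` (sample ids used), `life_table`,
#'   and internal bookkeeping reused by the score test.
#' @seealso [life_table_alpha()], [efficient_score_test()]
#' @export
fit_null <- function(data, tol = 1e-8, max_iter = 100L, max_halvings = 20L,
                     drop_uninformative = FALSE, trace = FALSE) {
  stop_not_grouped(data)
  q <- ncol(data$Z)

  keep <- rep(TRUE, data$n)
  if (q) {
    cc <- stats::complete.cases(data$Z)
    if (!all(cc)) {
      message(sum(!cc), " sample(s) with missing covariates excluded from the null fit")
      keep <- keep & cc
    }
  }
  if (drop_uninformative) keep <- keep & !(data$k == 1L & data$delta == 0L)
  sub <- gs_subset(data, which(keep))

  if (sum(sub$delta) == 0) stop("null model undefined: no events in the data")
  if (q) {
    qr_z <- qr(sub$Z)
    if (qr_z$rank < q) {
      bad <- colnames(sub$Z)[-qr_z$pivot[seq_len(qr_z$rank)]]
      if (is.null(bad) || !length(bad)) bad <- "(unnamed)"
      stop("covariate matrix is rank deficient; offending column(s): ",
           paste(bad, collapse = ", "))
    }
  }

  lt <- life_table_alpha(sub)
  est <- which(lt$class == "estimable")
  if (!length(est)) stop("null model undefined: no estimable interval")
  if (any(lt$class == "fixed_one")) {
    warning("interval(s) ", paste(which(lt$class == "fixed_one"), collapse = ", "),
            " have no events; alpha fixed at 1 (excluded from optimization)")
  }
  if (any(lt$class == "boundary_zero")) {
    warning("interval(s) ", paste(which(lt$class == "boundary_zero"), collapse = ", "),
            " have events but no survivors; alpha sits at the 0 boundary")
  }

  # log alpha vector: estimable from life table, fixed-one and boundary 0
  # (a = 0 is inert for boundary intervals because no sample passes through
  # them and their event terms are dropped below)
  a <- rep(0, sub$r)
  a[est] <- log(lt$alpha[est])
  delta_eff <- sub$delta
  delta_eff[sub$delta == 1L & lt$class[sub$k] == "boundary_zero"] <- 0L

  theta <- numeric(q)
  zeta <- log(-a[est])
  phi <- c(theta, zeta)
  ll <- gs_loglik(sub$k, delta_eff, sub$Z, NULL, numeric(0), theta, a)
  ll_path <- ll
  converged <- FALSE
  grad_norm <- Inf
  iter <- 0L

  repeat {
    eng <- gs_score_hess(sub$k, delta_eff, sub$Z, NULL, numeric(0),
                         theta, a, est)
    grad_norm <- max(abs(eng$score))
    if (grad_norm <= tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    step <- tryCatch(solve(eng$hess, eng$score),
                     error = function(e) gs_pinv(eng$hess) %*% eng$score)
    step <- drop(step)
    lam <- 1
    improved <- FALSE
    for (h in seq_len(max_halvings + 1L)) {
      cand <- phi - lam * step
      th_c <- cand[seq_len(q)]
      a_c <- a
      a_c[est] <- -exp(cand[q + seq_along(est)])
      ll_c <- gs_loglik(sub$k, delta_eff, sub$Z, NULL, numeric(0), th_c, a_c)
      if (is.finite(ll_c) && ll_c >= ll - 1e-12) {
        phi <- cand; theta <- th_c; a <- a_c; ll <- ll_c
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (trace) ll_path <- c(ll_path, ll)
    if (!improved) break
  }

  alpha_hat <- rep(NA_real_, sub$r)
  alpha_hat[lt$class == "fixed_one"] <- 1
  alpha_hat[lt$class == "boundary_zero"] <- 0
  alpha_hat[est] <- exp(a[est])

  structure(list(alpha_hat = alpha_hat,
                 theta_hat = stats::setNames(theta, colnames(sub$Z)),
                 zeta_hat = log(-a[est]),
                 est = est,
                 converged = converged,
                 n_iter = iter,
                 grad_norm = grad_norm,
                 loglik = ll,
                 fitted_on = sub$sample_id,
                 idx = which(keep),
                 life_table = lt,
                 a = a,
                 delta_eff = delta_eff,
                 ll_path = if (trace) ll_path else NULL,
                 r = sub$r, q = q, n = sub$n),
            class = "grouped_null_fit")
}

#' @export
print.grouped_null_fit <- function(x, ...) {
  cat("<grouped_null_fit> n = ", x$n, ", ", length(x$est),
      " free interval(s), ", x$q, " covariate(s)\n", sep = "")
  cat("  loglik ", format(x$loglik), "; ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iteration(s), |score| = ",
      format(x$grad_norm, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.grouped_null_fit <- function(x, ...) {
  th <- x$theta_hat
  nm <- names(th)
  if (is.null(nm) || !length(nm)) nm <- character(0)
  if (length(th) && !all(nzchar(nm))) nm <- paste0("z", seq_along(th))
  dplyr::bind_rows(
    tibble::tibble(term = nm, type = "covariate", estimate = unname(th)),
    tibble::tibble(term = paste0("alpha[", seq_along(x$alpha_hat), "]"),
                   type = "interval_survival", estimate = x$alpha_hat)
  )
}

#' @export
#' @importFrom generics glance
glance.grouped_null_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, n_iter = x$n_iter,
                 converged = x$converged, grad_norm = x$grad_norm,
                 n_free_intervals = length(x$est))
}

# Moore-Penrose pseudo-inverse via SVD (used when a Hessian block is singular)
gs_pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
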