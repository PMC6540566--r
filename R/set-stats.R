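# Gene / pathway set statistics built from per-sample efficient score
# contributions.

#' Upper tail probability of a weighted chi-square mixture
#'
#' `P(sum_l lambda_l chi^2_1 > q)` for positive weights `lambda`,
#' computed exactly by the Ruben series: with a scale `beta <= min(lambda)`
#' the distribution function expands as `sum_k e_k F_{m + 2k}(q / beta)`
#' where the `e_k` are non-negative mixture weights summing to one, so the
#' truncation error is bounded by the unassigned weight and the series is
#' run until that bound falls below `tol`. Falls back to the Liu et al.
#' four-moment chi-square approximation if the series converges too
#' slowly (extremely spread eigenvalues). A single eigenvalue is handled
#' directly through `pchisq`.
#'
#' @param q Observed value of the quadratic form.
#' @param lambda Mixture weights (eigenvalues), at least one positive.
#' @param tol Truncation bound for the series.
#' @param max_terms Series length cap before the Liu fallback engages.
#' @return A list with `p` and `method` (`"exact"`, `"ruben"` or `"liu"`).
#' @export
quadform_pvalue <- function(q, lambda, tol = 1e-11, max_terms = 20000L) {
  lambda <- lambda[abs(lambda) > max(abs(lambda)) * 1e-12]
  if (!length(lambda)) stop("all mixture weights are zero")
  if (any(lambda < 0)) stop("mixture weights must be non-negative")
  if (length(lambda) == 1L) {
    return(list(p = stats::pchisq(q / lambda, df = 1, lower.tail = FALSE),
                method = "exact"))
  }
  if (q <= 0) return(list(p = 1, method = "exact"))
  m <- length(lambda)
  beta <- 0.90625 * min(lambda)   # strictly inside (0, min lambda)
  ratio <- 1 - beta / lambda      # all in [0, 1)
  e <- numeric(max_terms)
  g <- numeric(max_terms)
  e[1] <- exp(0.5 * sum(log(beta / lambda)))
  cdf <- e[1] * stats::pchisq(q / beta, df = m)
  acc <- e[1]
  k <- 1L
  pow <- ratio
  while (1 - acc > tol && k < max_terms) {
    g[k] <- sum(pow)
    pow <- pow * ratio
    e[k + 1L] <- sum(g[seq_len(k)] * e[k:1]) / (2 * k)
    acc <- acc + e[k + 1L]
    cdf <- cdf + e[k + 1L] * stats::pchisq(q / beta, df = m + 2L * k)
    k <- k + 1L
  }
  if (1 - acc <= tol && is.finite(cdf)) {
    p <- 1 - cdf
    return(list(p = min(max(p, .Machine$double.xmin), 1), method = "ruben"))
  }
  list(p = liu_pvalue(q, lambda), method = "liu")
}

# Liu, Tang & Zhang (2009) moment-matched noncentral chi-square tail
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + d; sigma_x <- sqrt(2) * a
  t_star <- (q - mu_q) / sigma_q
  stats::pchisq(t_star * sigma_x + mu_x, df = l, ncp = d, lower.tail = FALSE)
}

#' Kernel (SKAT-type) set statistic from score contributions
#'
#' Variance-component test for a set of variants: with per-variant score
#' sums `S_j` (column sums of the per-sample efficient contributions) and
#' weights `w_j`, the statistic is `Q = sum_j w_j S_j^2`. Its null
#' distribution is the chi-square mixture with weights given by the
#' eigenvalues of `W^{1/2} Sigma W^{1/2}`, where `Sigma` is the sum of
#' per-sample outer products of the contribution rows (the non-centered
#' second moment: the efficient contributions have mean zero under the
#' null, and centering would subtract the realized score being tested);
#' the contributions are already projected for the nuisance parameters,
#' so no per-set refitting is needed. Default weights are the
#' squared Beta(1, 25) density at the variant MAFs, upweighting rare
#' variants.
#'
#' @param contributions n x m matrix of per-sample efficient score
#'   contributions for the set's variants (rows complete).
#' @param mafs Length-m minor allele frequencies (needed for the default
#'   weights).
#' @param weights Optional explicit non-negative weights (length m).
#' @param set_id Label carried into the result.
#' @return A tibble row: `set_id`, `m_variants`, `Q`, `pvalue`, `method`,
#'   plus the weights as an attribute.
#' @export
skat_test <- function(contributions, mafs = NULL, weights = NULL,
                      set_id = NA_character_) {
  U <- as.matrix(contributions)
  if (anyNA(U)) {
    keep <- stats::complete.cases(U)
    U <- U[keep, , drop = FALSE]
  }
  m <- ncol(U); n <- nrow(U)
  if (m < 1 || n < 2) stop("need at least one variant and two samples")
  if (is.null(weights)) {
    if (is.null(mafs)) stop("supply `mafs` for the default Beta(1,25) weights")
    if (length(mafs) != m) stop("length(mafs) != ncol(contributions)")
    weights <- stats::dbeta(mafs, 1, 25)^2
  }
  if (length(weights) != m || any(weights < 0)) {
    stop("`weights` must be m non-negative numbers")
  }
  S <- colSums(U)
  if (all(weights == 0)) {
    warning("all weights are zero; Q = 0, p = 1")
    out <- tibble::tibble(set_id = set_id, m_variants = m, Q = 0,
                          pvalue = 1, method = "skat")
    attr(out, "weights") <- weights
    return(out)
  }
  Q <- sum(weights * S^2)
  # null covariance of the score sums: sum of per-sample outer products
  # (non-centered: the efficient contributions have mean zero under H0, and
  # centering would subtract the realized score -- the very signal tested)
  Sigma <- crossprod(U)
  sw <- sqrt(weights)
  M <- Sigma * (sw %o% sw)
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-12]
  if (!length(lam)) stop("contribution covariance has rank 0")
  pv <- quadform_pvalue(Q, lam)
  out <- tibble::tibble(set_id = set_id, m_variants = m, Q = Q,
                        pvalue = min(max(pv$p, .Machine$double.xmin), 1),
                        method = "skat")
  attr(out, "weights") <- weights
  attr(out, "lambda") <- lam
  attr(out, "tail_method") <- pv$method
  out
}

#' Wrap a user-supplied set statistic
#'
#' Applies a user function mapping the contribution matrix to a list (or
#' named vector) with elements `Q` and `p`; the p-value is forced into
#' (0, 1]. Errors raised by the user function are captured and the set is
#' flagged failed instead of aborting.
#'
#' @inheritParams skat_test
#' @param statistic Function of the contribution matrix returning `Q` and
#'   `p`.
#' @return A tibble row like [skat_test()] with `method = "custom"` (or
#'   `"failed"`, carrying the error message in attribute `error`).
#' @export
custom_stat <- function(contributions, statistic, set_id = NA_character_) {
  U <- as.matrix(contributions)
  if (anyNA(U)) U <- U[stats::complete.cases(U), , drop = FALSE]
  res <- tryCatch(statistic(U), error = function(e) e)
  if (inherits(res, "error")) {
    out <- tibble::tibble(set_id = set_id, m_variants = ncol(U),
                          Q = NA_real_, pvalue = NA_real_, method = "failed")
    attr(out, "error") <- conditionMessage(res)
    return(out)
  }
  res <- as.list(res)
  if (!all(c("Q", "p") %in% names(res))) {
    stop("user statistic must return elements `Q` and `p`")
  }
  tibble::tibble(set_id = set_id, m_variants = ncol(U),
                 Q = as.numeric(res$Q),
                 pvalue = min(max(as.numeric(res$p), .Machine$double.xmin), 1),
                 method = "custom")
}

#' Gene/pathway-level statistics for a scan
#'
#' Computes a set-based statistic for each gene or pathway from the
#' per-sample score contributions of a variant scan. The default is the
#' kernel statistic of [skat_test()] with Beta(1, 25) MAF weights; any
#' user function mapping the contribution matrix to `(Q, p)` can be
#' supplied instead.
#'
#' @param scan A [scan_variants()] result obtained with
#'   `return_contributions = TRUE`.
#' @param sets Data frame with columns `set_id` and `variant_id`.
#' @param statistic Optional user statistic (see [custom_stat()]).
#' @param weights Optional explicit weights passed to [skat_test()]
#'   (recycled per set only when lengths match).
#' @return A tibble with one row per set: `set_id`, `m_variants`, `Q`,
#'   `pvalue`, `method`. Sets with no `ok` variants are flagged failed.
#' @export
gene_set_stats <- function(scan, sets, statistic = NULL, weights = NULL) {
  if (!inherits(scan, "grouped_scan")) stop("`scan` must come from scan_variants()")
  contrib <- attr(scan, "contributions")
  if (is.null(contrib)) {
    stop("scan was run without return_contributions = TRUE")
  }
  sets <- as.data.frame(sets)
  if (!all(c("set_id", "variant_id") %in% names(sets))) {
    stop("`sets` needs columns set_id and variant_id")
  }
  ok_tbl <- scan[scan$status == "ok", c("variant_id", "maf")]
  purrr::map_dfr(split(sets$variant_id, sets$set_id), function(vids) {
    vids <- intersect(unique(vids), ok_tbl$variant_id)
    if (!length(vids)) {
      return(tibble::tibble(m_variants = 0L, Q = NA_real_,
                            pvalue = NA_real_, method = "failed"))
    }
    U <- contrib[, vids, drop = FALSE]
    if (is.null(statistic)) {
      res <- skat_test(U, mafs = ok_tbl$maf[match(vids, ok_tbl$variant_id)],
                       weights = weights)
    } else {
      res <- custom_stat(U, statistic)
    }
    res[setdiff(names(res), "set_id")]
  }, .id = "set_id")
}
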