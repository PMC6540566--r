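#' Genome-wide scan of variants with the efficient score test
#'
#' Fits the null model once (unless supplied), then computes the efficient
#' score statistic, asymptotic p-value, and optionally the per-variant
#' effect-size MLE for every column of a genotype/dosage matrix, followed
#' by Bonferroni FWER adjustment and Storey q-values. Missing dosages are
#' handled per variant by complete-case restriction of the score sums and
#' information blocks; the global null MLE is reused (set
#' `refit_null = TRUE` for exact per-subset refitting). Each variant's
#' computation is independent of the partitioning, so results are
#' identical for any `cores` value and any column ordering.
#'
#' @param data A [grouped_data()] object.
#' @param genotypes n x m numeric matrix of dosages in `[0, 2]` (`NA` =
#'   missing), with `rownames` giving sample ids and `colnames` variant
#'   ids. Rows are aligned to `data` by id, never by position.
#' @param fit Optional precomputed [fit_null()] result.
#' @param beta_est Also compute the per-variant effect MLE and its
#'   standard error (slower).
#' @param refit_null Refit the nuisance parameters on each variant's
#'   complete cases instead of reusing the global null MLE.
#' @param cores Worker processes for variant-level parallelism.
#' @param return_contributions Attach the n x m matrix of per-sample
#'   efficient score contributions (needed by [gene_set_stats()]).
#' @param allow_missing_genotypes Permit phenotype samples absent from the
#'   genotype matrix (they are treated as missing for every variant).
#'   Without this flag such samples are an error.
#' @return A tibble of class `grouped_scan` with columns `variant_id`,
#'   `n`, `maf`, `stat`, `pvalue`, `fwer_p`, `qvalue`, `beta_hat`,
#'   `status`. `fwer_p` and `qvalue` are computed over the variants with
#'   `status == "ok"`. Attributes: `contributions` (if requested), `pi0`,
#'   and `null_fit`.
#' @examples
#' cfg <- sim_config(n = 120, beta = 0.4, maf = 0.3, c_max = 6, seed = 7)
#' sim <- simulate_grouped(cfg)
#' G <- cbind(snp1 = sim$x)
#' rownames(G) <- sim$data$sample_id
#' scan_variants(sim$data, G)
#' @export
scan_variants <- function(data, genotypes, fit = NULL, beta_est = FALSE,
                          refit_null = FALSE, cores = 1L,
                          return_contributions = FALSE,
                          allow_missing_genotypes = FALSE) {
  stop_not_grouped(data)
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes))) stop("`genotypes` needs sample ids as rownames")
  vid <- colnames(genotypes)
  if (is.null(vid)) vid <- paste0("v", seq_len(ncol(genotypes)))

  gid <- rownames(genotypes)
  extra <- setdiff(gid, data$sample_id)
  if (length(extra)) {
    message(length(extra), " genotyped sample(s) absent from the phenotype; dropped")
  }
  absent <- setdiff(data$sample_id, gid)
  if (length(absent)) {
    if (!allow_missing_genotypes) {
      stop("phenotype sample(s) missing from the genotype matrix: ",
           paste(utils::head(absent, 5), collapse = ", "),
           " (set allow_missing_genotypes = TRUE to treat them as missing)")
    }
  }
  pos <- match(data$sample_id, gid)
  G <- matrix(NA_real_, data$n, ncol(genotypes))
  G[!is.na(pos), ] <- genotypes[pos[!is.na(pos)], , drop = FALSE]

  if (is.null(fit)) fit <- fit_null(data)
  cache <- null_cache(data, fit)
  m <- ncol(G)

  one_variant <- function(j) {
    x <- G[, j]
    xs <- x[fit$idx]
    n_nm <- sum(!is.na(xs))
    maf <- if (n_nm) {
      f <- mean(xs, na.rm = TRUE) / 2
      min(f, 1 - f)
    } else NA_real_
    if (n_nm == 0) {
      return(list(n = 0L, maf = NA_real_, stat = NA_real_, pvalue = NA_real_,
                  beta_hat = NA_real_, se_beta = NA_real_, status = "failed",
                  contributions = rep(NA_real_, fit$n)))
    }
    if (refit_null) {
      keep <- fit$idx[!is.na(xs)]
      sub <- gs_subset(data, keep)
      fit_j <- tryCatch(suppressWarnings(fit_null(sub)), error = function(e) NULL)
      res <- if (is.null(fit_j)) {
        list(stat = NA_real_, pvalue = NA_real_, n = n_nm,
             contributions = NULL, status = "failed")
      } else {
        efficient_score_test(sub, x[keep], fit_j)
      }
      contrib <- rep(NA_real_, fit$n)
      if (!is.null(res$contributions)) {
        contrib[match(sub$sample_id, fit$fitted_on)] <- res$contributions
      }
    } else {
      res <- efficient_score_test(data, x, fit, cache = cache)
      contrib <- if (is.null(res$contributions)) rep(NA_real_, fit$n) else res$contributions
    }
    bh <- NA_real_; se <- NA_real_
    if (beta_est && res$status %in% c("ok", "boundary")) {
      be <- estimate_beta(data, x, fit)
      if (be$status == "ok" && be$converged) { bh <- be$beta_hat; se <- be$se }
    }
    list(n = res$n, maf = maf, stat = res$stat, pvalue = res$pvalue,
         beta_hat = bh, se_beta = se, status = res$status,
         contributions = contrib)
  }

  res <- if (cores > 1L) {
    parallel::mclapply(seq_len(m), one_variant, mc.cores = cores)
  } else {
    lapply(seq_len(m), one_variant)
  }

  out <- tibble::tibble(
    variant_id = vid,
    n = vapply(res, function(r) as.integer(r$n), 1L),
    maf = vapply(res, function(r) r$maf, 1.0),
    stat = vapply(res, function(r) r$stat, 1.0),
    pvalue = vapply(res, function(r) r$pvalue, 1.0),
    fwer_p = NA_real_,
    qvalue = NA_real_,
    beta_hat = vapply(res, function(r) r$beta_hat, 1.0),
    status = vapply(res, function(r) r$status, "")
  )
  ok <- out$status == "ok" & is.finite(out$pvalue)
  m_ok <- sum(ok)
  pi0 <- NA_real_
  if (m_ok) {
    out$fwer_p[ok] <- bonferroni_adjust(out$pvalue[ok], m_ok)
    qv <- suppressWarnings(storey_qvalues(out$pvalue[ok]))
    out$qvalue[ok] <- qv$q
    pi0 <- qv$pi0
  }
  class(out) <- c("grouped_scan", class(out))
  if (return_contributions) {
    cm <- vapply(res, function(r) r$contributions, numeric(fit$n))
    dimnames(cm) <- list(fit$fitted_on, vid)
    attr(out, "contributions") <- cm
  }
  attr(out, "pi0") <- pi0
  attr(out, "null_fit") <- fit
  out
}

#' @export
tidy.grouped_scan <- function(x, ...) {
  out <- x
  attr(out, "contributions") <- NULL
  attr(out, "pi0") <- NULL
  attr(out, "null_fit") <- NULL
  class(out) <- setdiff(class(out), "grouped_scan")
  out
}

#' Bonferroni family-wise error-rate adjustment
#'
#' `min(1, m * p)` elementwise.
#'
#' @param p Vector of p-values in (0, 1].
#' @param m Number of tests (defaults to `length(p)`; must be at least
#'   that).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p-values must lie in (0, 1]")
  if (m < length(p)) stop("`m` must be at least length(p)")
  pmin(1, m * p)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` on the lambda grid
#' `0.05, 0.10, ..., 0.95` with a cubic smoother evaluated at
#' `lambda = 0.95` (clipped to (0, 1]), then converts sorted p-values to
#' q-values by the step-up rule `q_(i) = min_{j >= i} pi0 m p_(j) / j`.
#' With fewer than 20 p-values the smoother is unreliable and `pi0 = 1`
#' is used with a warning (the q-values then reduce to
#' Benjamini-Hochberg adjusted p-values).
#'
#' @param p Vector of p-values in (0, 1].
#' @return A list with `q` (q-values in input order) and `pi0`.
#' @export
storey_qvalues <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (m < 20) {
    warning("fewer than 20 p-values; falling back to pi0 = 1")
    pi0 <- 1
  } else {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), 1.0)
    fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
    pi0 <- stats::predict(fit, x = 0.95)$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  list(q = q[order(o)], pi0 = pi0)
}

#' Expected vs observed quantiles of -log10 p
#'
#' Plain-text QQ export: sorted observed `-log10` p-values against the
#' uniform expectation `-log10((i - 0.5) / m)`.
#'
#' @param p Vector of p-values (NA dropped).
#' @return A tibble with columns `expected` and `observed`.
#' @export
qq_table <- function(p) {
  p <- sort(p[!is.na(p)])
  m <- length(p)
  tibble::tibble(expected = -log10((seq_len(m) - 0.5) / m),
                 observed = -log10(p))
}
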