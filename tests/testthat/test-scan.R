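# variant scan and multiple-testing adjustments

scan_fixture <- function(n = 120, m = 8, beta = 0, seed = 31) {
  sim <- sim_fixture(n = n, beta = beta, seed = seed)
  set.seed(seed + 1000)
  G <- vapply(seq_len(m), function(j) rbinom(n, 2, 0.3), numeric(n))
  G[, 1] <- sim$x
  dimnames(G) <- list(sim$data$sample_id, paste0("snp", seq_len(m)))
  list(sim = sim, G = G)
}

test_that("a one-variant scan reduces to the single test", {
  fx <- scan_fixture(m = 1)
  fit <- suppressWarnings(fit_null(fx$sim$data))
  sc <- suppressWarnings(scan_variants(fx$sim$data, fx$G, fit = fit))
  res <- efficient_score_test(fx$sim$data, fx$G[, 1], fit)
  expect_identical(nrow(sc), 1L)
  expect_equal(sc$pvalue, res$pvalue)
  expect_equal(sc$stat, res$stat)
  expect_equal(sc$fwer_p, res$pvalue)  # m = 1: identity
})

test_that("scan output carries the documented columns and statuses", {
  fx <- scan_fixture(m = 6)
  G <- fx$G
  G[, 2] <- 1          # monomorphic
  G[, 3] <- NA         # all missing
  G[5, 4] <- NA        # one missing call
  sc <- suppressWarnings(scan_variants(fx$sim$data, G, beta_est = TRUE))
  expect_identical(names(sc)[1:9],
                   c("variant_id", "n", "maf", "stat", "pvalue", "fwer_p",
                     "qvalue", "beta_hat", "status"))
  expect_identical(sc$status[2], "monomorphic")
  expect_identical(sc$status[3], "failed")
  expect_identical(sc$n[4], 119L)
  ok <- sc$status == "ok"
  expect_equal(sc$fwer_p[ok], pmin(1, sum(ok) * sc$pvalue[ok]))
  expect_true(all(is.finite(sc$beta_hat[ok])))
})

test_that("scan results are identical across worker counts and variant order", {
  fx <- scan_fixture(m = 10)
  s1 <- suppressWarnings(scan_variants(fx$sim$data, fx$G, cores = 1))
  s2 <- suppressWarnings(scan_variants(fx$sim$data, fx$G, cores = 2))
  expect_identical(tidy(s1), tidy(s2))

  perm <- c(7, 2, 9, 1, 10, 4, 3, 8, 5, 6)
  sp <- suppressWarnings(scan_variants(fx$sim$data, fx$G[, perm]))
  re <- tidy(sp)[match(s1$variant_id, sp$variant_id), ]
  expect_equal(re$stat, s1$stat)
  expect_equal(re$qvalue, s1$qvalue)
})

test_that("sample alignment is by id and mismatches are fatal", {
  fx <- scan_fixture(m = 3)
  G <- fx$G
  # permuting genotype rows must not change anything (id join)
  perm <- sample(nrow(G))
  s1 <- suppressWarnings(scan_variants(fx$sim$data, G))
  s2 <- suppressWarnings(scan_variants(fx$sim$data, G[perm, ]))
  expect_equal(s2$stat, s1$stat)

  rownames(G)[1] <- "stranger"
  expect_error(suppressMessages(scan_variants(fx$sim$data, G)),
               "missing from the genotype")
  expect_s3_class(
    suppressMessages(suppressWarnings(
      scan_variants(fx$sim$data, G, allow_missing_genotypes = TRUE))),
    "grouped_scan")
})

test_that("per-variant null refitting changes the subset fit only when samples drop", {
  fx <- scan_fixture(m = 2)
  G <- fx$G
  s_global <- suppressWarnings(scan_variants(fx$sim$data, G))
  s_refit <- suppressWarnings(scan_variants(fx$sim$data, G, refit_null = TRUE))
  # no missingness: the refitted null is the global null
  expect_equal(s_refit$stat, s_global$stat, tolerance = 1e-8)
  G[1:10, 2] <- NA
  s_refit2 <- suppressWarnings(scan_variants(fx$sim$data, G, refit_null = TRUE))
  s_global2 <- suppressWarnings(scan_variants(fx$sim$data, G))
  expect_equal(s_refit2$stat[1], s_global2$stat[1], tolerance = 1e-8)
  expect_false(isTRUE(all.equal(s_refit2$stat[2], s_global2$stat[2])))
})

test_that("Bonferroni adjustment follows min(1, m p)", {
  expect_equal(bonferroni_adjust(0.001, m = 100), 0.1)
  expect_equal(bonferroni_adjust(0.02, m = 100), 1)
  expect_equal(bonferroni_adjust(0.05, m = 1), 0.05)
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is forced to 1", {
  p <- c(0.002, 0.8, 0.04, 0.3, 0.9, 0.011)
  expect_warning(qv <- storey_qvalues(p), "pi0 = 1")
  expect_equal(qv$pi0, 1)
  expect_equal(qv$q, stats::p.adjust(p, "BH"))
  expect_warning(q1 <- storey_qvalues(rep(1, 5))$q)
  expect_equal(q1, rep(1, 5))
})

test_that("q-values match an independent step-by-step implementation", {
  set.seed(99)
  p <- runif(100)
  qv <- storey_qvalues(p)

  # reference: explicit lambda-grid pi0 smoother and step-up minimum
  lam <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- sapply(lam, function(l) sum(p > l) / (length(p) * (1 - l)))
  pi0 <- min(max(predict(smooth.spline(lam, pi0_l, df = 3), x = 0.95)$y,
                 .Machine$double.eps), 1)
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  qs[m] <- min(pi0 * ps[m], 1)
  for (i in (m - 1):1) qs[i] <- min(pi0 * m * ps[i] / i, qs[i + 1])
  qref <- numeric(m)
  qref[o] <- qs
  expect_equal(qv$pi0, pi0, tolerance = 1e-10)
  expect_equal(qv$q, qref, tolerance = 1e-10)
})

test_that("the QQ export pairs sorted observations with uniform quantiles", {
  p <- c(0.5, 0.01, 0.2, NA)
  qq <- qq_table(p)
  expect_identical(nrow(qq), 3L)
  expect_equal(qq$observed, -log10(c(0.01, 0.2, 0.5)))
  expect_equal(qq$expected, -log10((1:3 - 0.5) / 3))
})
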