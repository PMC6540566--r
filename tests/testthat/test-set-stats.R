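# gene/pathway set statistics

contrib_fixture <- function(n = 300, m = 3, beta = 0, seed = 41) {
  sim <- sim_fixture(n = n, beta = beta, seed = seed)
  set.seed(seed + 500)
  G <- vapply(seq_len(m), function(j) rbinom(n, 2, runif(1, 0.1, 0.4)),
              numeric(n))
  dimnames(G) <- list(sim$data$sample_id, paste0("snp", seq_len(m)))
  sc <- suppressWarnings(
    scan_variants(sim$data, G, return_contributions = TRUE))
  list(scan = sc, U = attr(sc, "contributions"), maf = sc$maf)
}

test_that("a single-variant set reduces to the marginal test under the empirical variance", {
  fx <- contrib_fixture(m = 1)
  res <- skat_test(fx$U, mafs = fx$maf, weights = 1)
  S <- sum(fx$U[, 1])
  v <- sum(fx$U[, 1]^2)
  p_marg <- pchisq(S^2 / v, df = 1, lower.tail = FALSE)
  expect_equal(res$pvalue, p_marg, tolerance = 1e-8)
  expect_equal(res$Q, S^2)
})

test_that("all-zero weights degenerate to Q = 0, p = 1", {
  fx <- contrib_fixture(m = 2)
  expect_warning(res <- skat_test(fx$U, weights = c(0, 0)), "zero")
  expect_identical(res$Q, 0)
  expect_identical(res$pvalue, 1)
})

test_that("the mixture tail probability matches Monte-Carlo draws from the fitted null", {
  fx <- contrib_fixture(m = 3)
  res <- skat_test(fx$U, mafs = fx$maf)
  lam <- attr(res, "lambda")
  set.seed(7)
  B <- 1e5
  draws <- colSums(lam * matrix(rchisq(B * length(lam), df = 1),
                                nrow = length(lam)))
  p_mc <- mean(draws > res$Q)
  se <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(res$pvalue - p_mc), 3 * max(se, 1e-4))
})

test_that("the series expansion agrees with the exact equal-eigenvalue tail", {
  # two equal eigenvalues: 2 chi^2_2 in closed form
  pr <- quadform_pvalue(5, c(2, 2))
  expect_identical(pr$method, "ruben")
  expect_equal(pr$p, pchisq(2.5, df = 2, lower.tail = FALSE),
               tolerance = 1e-9)
  # Liu approximation is in the right neighbourhood
  expect_equal(liu_pvalue(5, c(2, 2)), pr$p, tolerance = 0.02)
})

test_that("a user statistic reproducing the built-in kernel matches it exactly", {
  fx <- contrib_fixture(m = 3)
  w <- stats::dbeta(fx$maf, 1, 25)^2
  own <- function(U) {
    r <- skat_test(U, weights = w)
    list(Q = r$Q, p = r$pvalue)
  }
  a <- skat_test(fx$U, mafs = fx$maf)
  b <- custom_stat(fx$U, own)
  expect_equal(b$Q, a$Q)
  expect_equal(b$pvalue, a$pvalue)
  expect_identical(b$method, "custom")

  cst <- custom_stat(fx$U, function(U) list(Q = 0, p = 1))
  expect_identical(cst$Q, 0)
  expect_identical(cst$pvalue, 1)

  failed <- custom_stat(fx$U, function(U) stop("boom"))
  expect_identical(failed$method, "failed")
  expect_match(attr(failed, "error"), "boom")
})

test_that("a sign-flip resampling p-value brackets the analytic one", {
  fx <- contrib_fixture(m = 3, seed = 47)
  perm_stat <- function(U) {
    S <- colSums(U)
    Q <- sum(S^2)
    set.seed(123)
    qb <- replicate(500, {
      s <- sample(c(-1, 1), nrow(U), replace = TRUE)
      sum(colSums(U * s)^2)
    })
    list(Q = Q, p = max(mean(qb >= Q), 1 / 501))
  }
  pp <- custom_stat(fx$U, perm_stat)$pvalue
  pa <- skat_test(fx$U, weights = rep(1, 3))$pvalue
  se <- sqrt(pa * (1 - pa) / 500)
  expect_lt(abs(pp - pa), max(3 * se, 0.02))
})

test_that("set p-values are uniform under the global null", {
  sim <- sim_fixture(n = 300, beta = 0, seed = 53)
  n_sets <- 2000L
  set.seed(54)
  G <- matrix(rbinom(300 * 3 * n_sets, 2, 0.25), nrow = 300)
  dimnames(G) <- list(sim$data$sample_id, paste0("v", seq_len(ncol(G))))
  sc <- suppressWarnings(scan_variants(sim$data, G, return_contributions = TRUE))
  sets <- tibble::tibble(set_id = rep(paste0("g", seq_len(n_sets)), each = 3),
                         variant_id = colnames(G))
  gs <- gene_set_stats(sc, sets)
  expect_identical(nrow(gs), n_sets)
  ks <- suppressWarnings(stats::ks.test(gs$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Q is invariant to sample order and contribution stream splits", {
  fx <- contrib_fixture(m = 3)
  a <- skat_test(fx$U, mafs = fx$maf)
  perm <- sample(nrow(fx$U))
  b <- skat_test(fx$U[perm, ], mafs = fx$maf)
  expect_equal(b$Q, a$Q, tolerance = 1e-12)
  expect_equal(b$pvalue, a$pvalue, tolerance = 1e-10)
})

test_that("sets resolve against scan results by variant id", {
  fx <- contrib_fixture(m = 4)
  sets <- tibble::tibble(
    set_id = c("a", "a", "b", "b", "c"),
    variant_id = c("snp1", "snp2", "snp3", "nonexistent", "alsomissing"))
  gs <- gene_set_stats(fx$scan, sets)
  expect_identical(gs$m_variants[gs$set_id == "a"], 2L)
  expect_identical(gs$m_variants[gs$set_id == "b"], 1L)
  expect_identical(gs$method[gs$set_id == "c"], "failed")
})
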