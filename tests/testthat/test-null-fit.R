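# null-model nuisance estimation

test_that("life-table estimator reproduces the closed form", {
  d <- make_data(c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3),
                 c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), r = 3)
  lt <- life_table_alpha(d)
  expect_equal(lt$alpha[1:2], c(1 - 2 / 10, 1 - 3 / 8))
  expect_identical(lt$class[3], "undefined")  # nobody at risk beyond tau

  # fit_null without covariates must agree exactly
  fit <- fit_null(d)
  expect_true(fit$converged)
  expect_equal(fit$alpha_hat[1:2], c(0.8, 0.625), tolerance = 1e-10)
  expect_identical(fit$n_iter, 0L)  # the initializer is already the MLE
})

test_that("all samples censored at time 0 leave nothing to estimate", {
  d <- make_data(rep(1, 5), rep(0, 5), r = 2)
  expect_warning(lt <- life_table_alpha(d), "empty")
  expect_true(attr(lt, "empty_estimable"))
  expect_error(fit_null(d), "no events")
})

test_that("fit with covariates matches a generic optimizer", {
  sim <- sim_fixture(n = 200, beta = 0, seed = 5)
  fit <- suppressWarnings(fit_null(sim$data))
  est <- fit$est; q <- 2
  nll <- function(par) {
    alpha <- ifelse(is.na(fit$alpha_hat), 1, pmax(fit$alpha_hat, 1e-12))
    alpha[est] <- exp(-exp(par[q + seq_along(est)]))
    -grouped_loglik(sim$data, theta = par[1:q], alpha = alpha)
  }
  o <- stats::optim(c(0, 0, log(-log(fit$alpha_hat[est]))), nll,
                    method = "BFGS", control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(unname(fit$theta_hat), o$par[1:q], tolerance = 1e-5)
  expect_equal(log(-log(fit$alpha_hat[est])), o$par[q + seq_along(est)],
               tolerance = 1e-5)
  expect_equal(fit$loglik, -o$value, tolerance = 1e-8)
})

test_that("duplicating every sample leaves the estimate unchanged", {
  sim <- sim_fixture(n = 120, seed = 8)
  td <- tidy(sim$data)
  td2 <- dplyr::bind_rows(td, dplyr::mutate(td, sample_id = paste0(sample_id, "b")))
  d2 <- grouped_data(td2[1:3], td2[c(1, 4, 5)], r = sim$data$r)
  f1 <- suppressWarnings(fit_null(sim$data))
  f2 <- suppressWarnings(fit_null(d2))
  expect_equal(f2$theta_hat, f1$theta_hat, tolerance = 1e-7)
  expect_equal(f2$alpha_hat, f1$alpha_hat, tolerance = 1e-7)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("estimates transform correctly under sample permutation and covariate scaling", {
  sim <- sim_fixture(n = 150, seed = 9)
  td <- tidy(sim$data)
  f1 <- suppressWarnings(fit_null(sim$data))

  # permutation: identical estimates
  perm <- sample(nrow(td))
  dp <- grouped_data(td[perm, 1:3], td[perm, c(1, 4, 5)], r = sim$data$r)
  fp <- suppressWarnings(fit_null(dp))
  expect_equal(fp$theta_hat, f1$theta_hat, tolerance = 1e-8)
  expect_equal(fp$alpha_hat, f1$alpha_hat, tolerance = 1e-8)

  # scaling a column by a: theta scales by 1/a, alpha unchanged
  td_s <- td; td_s$z1 <- td$z1 * 4
  ds <- grouped_data(td_s[1:3], td_s[c(1, 4, 5)], r = sim$data$r)
  fs <- suppressWarnings(fit_null(ds))
  expect_equal(unname(fs$theta_hat["z1"]), unname(f1$theta_hat["z1"]) / 4,
               tolerance = 1e-7)
  expect_equal(fs$alpha_hat, f1$alpha_hat, tolerance = 1e-7)

  # centering a column by c: the baseline absorbs the shift,
  # alpha' = alpha^exp(theta c); theta and the log-likelihood unchanged
  cc <- mean(td$z1)
  td_c <- td; td_c$z1 <- td$z1 - cc
  dc <- grouped_data(td_c[1:3], td_c[c(1, 4, 5)], r = sim$data$r)
  fc <- suppressWarnings(fit_null(dc))
  expect_equal(fc$theta_hat, f1$theta_hat, tolerance = 1e-6)
  expect_equal(fc$loglik, f1$loglik, tolerance = 1e-8)
  est <- f1$est
  expect_equal(fc$alpha_hat[est],
               f1$alpha_hat[est]^exp(unname(f1$theta_hat["z1"]) * cc),
               tolerance = 1e-6)
})

test_that("event-free intervals are fixed at alpha = 1 with a warning", {
  d <- make_data(c(1, 1, 3, 3, 3, 4, 4), c(1, 1, 1, 1, 0, 0, 0), r = 4)
  expect_warning(fit <- fit_null(d), "no events")
  expect_identical(fit$alpha_hat[2], 1)
  expect_false(2L %in% fit$est)
})

test_that("degenerate inputs raise informative errors", {
  d <- make_data(c(1, 2, 3), c(0, 0, 0), r = 3)
  expect_error(fit_null(d), "no events")

  sim <- sim_fixture(n = 80, seed = 2)
  td <- tidy(sim$data)
  td$z3 <- 2 * td$z1   # collinear
  dd <- grouped_data(td[1:3], td[c(1, 4, 5, 6)], r = sim$data$r)
  expect_error(suppressWarnings(fit_null(dd)), "z3")
})

test_that("the Newton path never decreases the log-likelihood", {
  sim <- sim_fixture(n = 150, seed = 12)
  fit <- suppressWarnings(fit_null(sim$data, trace = TRUE))
  expect_true(all(diff(fit$ll_path) >= -1e-10))
})

test_that("samples with missing covariates are excluded with a message", {
  sim <- sim_fixture(n = 100, seed = 14)
  td <- tidy(sim$data)
  td$z1[c(3, 7)] <- NA
  d <- grouped_data(td[1:3], td[c(1, 4, 5)], r = sim$data$r)
  expect_message(fit <- suppressWarnings(fit_null(d)), "2 sample")
  expect_identical(length(fit$fitted_on), 98L)
  expect_false(any(c("s003", "s007") %in% fit$fitted_on))
})
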