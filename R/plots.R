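# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' QQ plot of a variant scan
#'
#' Expected versus observed `-log10` p-values over the `ok` variants,
#' with the identity reference line.
#'
#' @param object A [scan_variants()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grouped_scan <- function(object, ...) {
  qq <- qq_table(object$pvalue[object$status == "ok"])
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Power / rejection-rate curves from an operating-characteristics run
#'
#' Rejection fraction against the true effect size, one curve per MAF,
#' with binomial Monte-Carlo error bars.
#'
#' @param object An [operating_characteristics()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grouped_opchar <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$reject,
                                   colour = factor(.data$maf))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$reject - 2 * .data$reject_se),
      ymax = pmin(1, .data$reject + 2 * .data$reject_se))) +
    ggplot2::labs(x = expression(beta), y = "rejection fraction",
                  colour = "MAF") +
    ggplot2::theme_minimal()
}

#' @export
tidy.grouped_opchar <- function(x, ...) {
  out <- x
  out$replicates <- NULL
  class(out) <- setdiff(class(out), "grouped_opchar")
  tibble::as_tibble(out)
}

#' Baseline survival curve from a null fit
#'
#' Step plot of the cumulative baseline survival
#' `prod_{j <= k} alpha_hat_j` across intervals.
#'
#' @param object A [fit_null()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grouped_null_fit <- function(object, ...) {
  a <- object$alpha_hat
  known <- !is.na(a)
  surv <- cumprod(ifelse(known, a, 1))
  df <- tibble::tibble(interval = c(0, seq_along(a)[known]),
                       survival = c(1, surv[known]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "interval", y = "baseline survival") +
    ggplot2::theme_minimal()
}
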