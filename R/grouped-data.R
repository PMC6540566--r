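#' Assemble a grouped failure-time dataset
#'
#' Bundles per-sample grouped outcomes with optional baseline covariates.
#' A grouped outcome is an interval index `k` in `1..r` together with an
#' event flag: `(k = j, event = 1)` means the event occurred inside the
#' j-th interval `[t_{j-1}, t_j)`, while `(k = j, event = 0)` means the
#' sample was right-censored at the interval's start `t_{j-1}`. The pair
#' `(k = 1, event = 0)` is legal and denotes uninformative censoring at
#' time 0; such samples contribute a likelihood factor of exactly 1.
#'
#' @param pheno Data frame with columns `sample_id`, `interval` (1-based
#'   integer) and `event` (0/1).
#' @param covariates Optional data frame with a `sample_id` column and one
#'   or more numeric baseline covariate columns, joined to `pheno` by id.
#'   No intercept is ever added: the baseline is absorbed by the interval
#'   survival probabilities.
#' @param r Number of intervals. Defaults to the largest interval index
#'   observed.
#'
#' @return An object of class `grouped_data`: a list with elements
#'   `sample_id`, `k`, `delta`, `Z` (n x q covariate matrix, possibly with
#'   0 columns), `r` and `n`.
#' @examples
#' ph <- tibble::tibble(sample_id = c("a", "b", "c"),
#'                      interval = c(1, 2, 3), event = c(1, 1, 0))
#' grouped_data(ph)
#' @export
grouped_data <- function(pheno, covariates = NULL, r = NULL) {
  pheno <- as.data.frame(pheno)
  need <- c("sample_id", "interval", "event")
  missing_cols <- setdiff(need, names(pheno))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  id <- as.character(pheno$sample_id)
  if (anyDuplicated(id)) {
    stop("duplicate sample ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  k <- pheno$interval
  if (!is.numeric(k) || any(!is.finite(k)) || any(k != round(k)) || any(k < 1)) {
    stop("`interval` must be a positive integer index")
  }
  k <- as.integer(k)
  delta <- pheno$event
  if (!is.numeric(delta) || !all(delta %in% c(0, 1))) {
    stop("`event` must be 0 or 1")
  }
  delta <- as.integer(delta)
  if (is.null(r)) r <- max(k)
  r <- as.integer(r)
  if (r < 1 || any(k > r)) stop("interval index exceeds r = ", r)

  n <- length(k)
  if (n < 1) stop("empty dataset")

  if (is.null(covariates)) {
    Z <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    covariates <- as.data.frame(covariates)
    if (!"sample_id" %in% names(covariates)) {
      stop("covariate table lacks a `sample_id` column")
    }
    cid <- as.character(covariates$sample_id)
    if (anyDuplicated(cid)) stop("duplicate sample ids in covariate table")
    pos <- match(id, cid)
    if (anyNA(pos)) {
      stop("samples without covariate rows: ",
           paste(utils::head(id[is.na(pos)], 5), collapse = ", "))
    }
    zz <- covariates[pos, setdiff(names(covariates), "sample_id"), drop = FALSE]
    if (!all(vapply(zz, is.numeric, TRUE))) stop("covariates must be numeric")
    Z <- as.matrix(zz)
    rownames(Z) <- NULL
  }

  structure(list(sample_id = id, k = k, delta = delta, Z = Z,
                 r = r, n = n),
            class = "grouped_data")
}

#' @export
print.grouped_data <- function(x, ...) {
  cat("<grouped_data> ", x$n, " samples, ", x$r, " intervals, ",
      ncol(x$Z), " covariate(s); ", sum(x$delta), " events\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.grouped_data <- function(x, ...) {
  out <- tibble::tibble(sample_id = x$sample_id, interval = x$k, event = x$delta)
  if (ncol(x$Z)) out <- dplyr::bind_cols(out, tibble::as_tibble(x$Z))
  out
}

# subset a grouped_data by row index, keeping r fixed
gs_subset <- function(data, idx) {
  structure(list(sample_id = data$sample_id[idx],
                 k = data$k[idx], delta = data$delta[idx],
                 Z = data$Z[idx, , drop = FALSE],
                 r = data$r, n = length(idx)),
            class = "grouped_data")
}

stop_not_grouped <- function(data) {
  if (!inherits(data, "grouped_data")) {
    stop("`data` must be a grouped_data object (see grouped_data())")
  }
  invisible(data)
}
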