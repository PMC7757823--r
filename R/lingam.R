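#' Differential-entropy approximation for a standardized sample
#'
#' Maximum-entropy approximation of the differential entropy (in nats) of a
#' unit-variance sample:
#' `H(x) = (1 + log 2*pi)/2 - 79.047 (E[log cosh x] - 0.37457)^2`
#' `- 7.4129 (E[x exp(-x^2/2)])^2`,
#' with expectations taken as plain sample means (no density estimation).
#' The first penalty term captures symmetric (kurtosis-like) departure from
#' Gaussianity, the second asymmetric (skewness-like) departure; both
#' vanish for a standard normal, where the value approaches
#' `(1 + log 2*pi)/2 ~ 1.4189`, the entropy of N(0, 1) and the maximum over
#' unit-variance distributions.
#'
#' @param x Numeric sample, assumed standardized (mean 0, SD 1); callers
#'   are responsible for standardizing.
#' @return Entropy approximation in nats (scalar).
#' @export
#' @examples
#' set.seed(1)
#' entropy_approx(scale(rnorm(1e4))[, 1])
entropy_approx <- function(x) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    stop("entropy_approx(): input must be finite numeric", call. = FALSE)
  }
  cpp_entropy(as.numeric(x))
}

#' Least-squares residual of one variable on another
#'
#' Residual `xi - b * xj` with `b = cov(xi, xj) / var(xj)`; the residual has
#' exactly zero sample covariance with `xj`.
#'
#' @param xi,xj Numeric samples of equal length (at least 3).
#' @param standardize If `TRUE`, the residual is re-standardized to mean 0,
#'   SD 1 (the form the entropy approximation expects).
#' @return Numeric residual vector.
#' @export
residual_on <- function(xi, xj, standardize = FALSE) {
  stopifnot(length(xi) == length(xj), length(xi) >= 3)
  v <- stats::var(xj)
  if (!is.finite(v) || v <= 0) {
    stop("residual_on(): xj has zero variance", call. = FALSE)
  }
  r <- xi - (stats::cov(xi, xj) / v) * xj
  if (standardize) r <- (r - mean(r)) / stats::sd(r)
  r
}

#' Pairwise causal-direction measure
#'
#' Entropy-based evidence that `xi` is the source of `xj`:
#' `m = [H(xj) + H(r_i(j))] - [H(xi) + H(r_j(i))]`,
#' where `r_i(j)` is the standardized residual of `xi` regressed on `xj`.
#' Positive `m` favors `xi` as the cause of `xj`; the measure is exactly
#' antisymmetric in its arguments (the joint-entropy terms of the
#' underlying Kullback-Leibler divergences cancel, so no joint entropy is
#' ever computed).  For jointly Gaussian pairs the measure converges to 0:
#' direction is not identifiable without non-Gaussianity.
#'
#' Both inputs are standardized internally, and residuals are
#' re-standardized before entropy evaluation.
#'
#' @param xi,xj Numeric samples of equal length.
#' @return Scalar measure; positive means `xi` precedes `xj`.
#' @export
#' @examples
#' set.seed(1)
#' x1 <- (rexp(5e3) - rexp(5e3)) / sqrt(2)
#' x2 <- 0.8 * x1 + (rexp(5e3) - rexp(5e3)) / sqrt(2)
#' pairwise_measure(x1, x2) > 0
pairwise_measure <- function(xi, xj) {
  m <- cpp_measure_matrix(std_cols(cbind(i = xi, j = xj)))
  m[1, 2]
}

#' Pairwise measure matrix over a checkup table
#'
#' Computes the full antisymmetric matrix of pairwise causal-direction
#' measures over the index columns: entry `[i, j]` is the evidence that
#' index `i` precedes index `j` (see [pairwise_measure()]).  Columns are
#' standardized internally.
#'
#' @param data Checkup tibble (an `id` column is ignored) or numeric
#'   matrix.
#' @return A p x p antisymmetric matrix with index dimnames.
#' @export
pairwise_measure_matrix <- function(data) {
  X <- if (is.matrix(data)) data else as_index_matrix(data)
  m <- cpp_measure_matrix(std_cols(X))
  dimnames(m) <- list(colnames(X), colnames(X))
  m
}

#' Root scores for every candidate first variable
#'
#' The root-selection criterion `M(x_i; U) = -sum_j min(0, m[i, j])^2`:
#' zero when every pairwise measure favors `i` as a source of every other
#' active variable (the ideal exogenous variable), and increasingly
#' negative the more strongly some other variable appears to cause `i`.
#' The estimated root is the argmax.
#'
#' @param data Checkup tibble or numeric matrix of active variables.
#' @return A tibble with columns `index` and `m_score`, in input column
#'   order.
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 2000, seed = 1)
#' root_scores(generate_standardized(cfg))
root_scores <- function(data) {
  m <- pairwise_measure_matrix(data)
  score <- -rowSums(pmin(m, 0)^2)
  tibble::tibble(index = rownames(m), m_score = unname(score))
}

#' Select the root (most exogenous) variable
#'
#' @param data Checkup tibble or numeric matrix.
#' @return The name of the index maximizing the root score; exact ties are
#'   broken by column order.
#' @export
select_root <- function(data) {
  s <- root_scores(data)
  if (nrow(s) == 1) return(s$index)
  s$index[which.max(s$m_score)]
}

#' Deflate a table by its root variable
#'
#' Replaces every non-root variable by its least-squares residual on the
#' root (zero covariance with the root by construction) and
#' re-standardizes, removing the root from the active set.  Repeated
#' deflation by successive roots is equivalent to sequential Gram-Schmidt
#' residualization.
#'
#' @param data Checkup tibble or numeric matrix.
#' @param root Name of the root column.
#' @return Tibble (or matrix, matching the input) over the remaining
#'   variables, standardized.
#' @export
deflate <- function(data, root) {
  X <- if (is.matrix(data)) data else as_index_matrix(data)
  stopifnot(root %in% colnames(X))
  Xs <- std_cols(X)
  r <- Xs[, root]
  rest <- Xs[, setdiff(colnames(Xs), root), drop = FALSE]
  slopes <- as.numeric(crossprod(r, rest)) / sum(r * r)
  res <- rest - outer(r, slopes)
  res <- std_cols(res)
  if (is.matrix(data)) res else tibble::as_tibble(as.data.frame(res))
}

#' Estimate the causal order of the checkup indices
#'
#' The DirectLiNGAM ordering loop: standardize, pick the root by the
#' pairwise-measure criterion ([select_root()]), deflate
#' ([deflate()]), and repeat on the shrinking active set until all
#' variables are ordered.  The output is always a permutation of the index
#' columns; on data violating the non-Gaussianity assumption the returned
#' order is arbitrary and unstable across resamples (use
#' [bootstrap_lingam()] to measure stability).  The estimate is invariant
#' to affine rescaling of input columns.
#'
#' @param data Checkup tibble (an `id` column is ignored) or numeric
#'   matrix; at least 1 column, complete cases only.
#' @return Character vector: index names from most exogenous to most
#'   downstream.
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 5000, seed = 1)
#' estimate_order(generate_standardized(cfg))
estimate_order <- function(data) {
  X <- if (is.matrix(data)) data else as_index_matrix(data)
  p <- ncol(X)
  if (p == 0) stop("estimate_order(): no index columns", call. = FALSE)
  if (anyNA(X)) stop("estimate_order(): missing values; clean first",
                     call. = FALSE)
  order_out <- character(p)
  active <- std_cols(X)
  for (k in seq_len(p - 1)) {
    m <- cpp_measure_matrix(active)
    score <- -rowSums(pmin(m, 0)^2)
    root_j <- which.max(score)
    root <- colnames(active)[root_j]
    order_out[k] <- root
    r <- active[, root_j]
    rest <- active[, -root_j, drop = FALSE]
    slopes <- as.numeric(crossprod(r, rest)) / sum(r * r)
    active <- std_cols(rest - outer(r, slopes))
  }
  order_out[p] <- setdiff(colnames(X), order_out)[1]
  order_out
}
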