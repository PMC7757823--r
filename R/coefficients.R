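# OLS on predecessors via the normal equations (no intercept: columns are
# standardized/centered upstream).  Returns coefficients, SEs, p-values.
ols_on_predecessors <- function(y, X) {
  n <- length(y)
  k <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  R <- chol(XtX)
  w <- backsolve(R, forwardsolve(t(R), Xty))
  resid <- y - X %*% w
  df <- n - k
  s2 <- sum(resid^2) / df
  XtX_inv <- chol2inv(R)
  se <- sqrt(pmax(diag(XtX_inv), 0) * s2)
  t <- as.numeric(w) / se
  list(coef = as.numeric(w), se = se,
       p = 2 * stats::pt(-abs(t), df = df))
}

# Elasticnet solve for one regression under the objective
#   (1/(2N)) * RSS + lambda * (alpha |w| + (1 - alpha) w^2 / 2)
# (glmnet's parameterization).  Single-predictor case has a closed form;
# otherwise glmnet does the coordinate descent.
enet_on_predecessors <- function(y, X, lambda, alpha) {
  n <- length(y)
  if (ncol(X) == 1) {
    rho <- sum(X[, 1] * y) / n
    denom <- sum(X[, 1]^2) / n + lambda * (1 - alpha)
    w <- sign(rho) * max(abs(rho) - lambda * alpha, 0) / denom
    return(w)
  }
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-12)
  as.numeric(fit$beta[, 1])
}

#' Fit the structural coefficient matrix for a given causal order
#'
#' Ordered multiple regression: each index is regressed on the set of
#' indices preceding it in the causal order, giving the strictly
#' lower-triangular structural matrix B of the linear SEM
#' `x = B x + e`.  With `lambda = 0` (the default) the fit is exact
#' ordinary least squares via the normal equations.  With `lambda > 0` the
#' elasticnet objective
#' `(1/(2N)) RSS + lambda * (alpha |w| + (1 - alpha) w^2 / 2)`
#' is minimized (glmnet's parameterization; the 1/N data term keeps
#' `lambda` comparable across sample sizes).  If `lambda` or `alpha` has
#' length > 1 the pair is selected by cross-validation first (see
#' [select_regularization()]).
#'
#' Unpenalized per-edge standard errors and p-values are always computed
#' alongside (penalized estimators lack standard errors); significance
#' flags start all-`TRUE` until [significance_filter()] is applied.
#'
#' @param data Standardized checkup tibble or numeric matrix.
#' @param order Character vector: causal order (a permutation of the index
#'   columns), e.g. from [estimate_order()].
#' @param lambda,alpha Elasticnet penalty and mixing weight; vectors are
#'   treated as grids for cross-validated selection.
#' @param nfolds,cv_seed Cross-validation controls, used only when a grid
#'   is supplied.
#' @return A `lingam_fit`: list with `order`, `B` (p x p matrix in causal-
#'   order coordinates, rows influenced by columns), `se`, `p_value`,
#'   `significant` (logical matrix), `lambda`, `alpha`, `n`.
#' @seealso [tidy.lingam_fit()], [significance_filter()], [direct_lingam()]
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 3000, seed = 1)
#' tbl <- generate_standardized(cfg)
#' fit <- fit_b_matrix(tbl, default_causal_order())
#' round(fit$B["HbA1c", "fBG"], 2)
fit_b_matrix <- function(data, order, lambda = 0, alpha = 0.5,
                         nfolds = 5, cv_seed = 1L) {
  X <- if (is.matrix(data)) data else as_index_matrix(data)
  stopifnot(setequal(order, colnames(X)), !anyDuplicated(order))
  X <- std_cols(X[, order, drop = FALSE])
  n <- nrow(X)
  p <- ncol(X)
  if (length(lambda) > 1 || length(alpha) > 1) {
    sel <- select_regularization(X, order, lambda_grid = lambda,
                                 alpha_grid = alpha, nfolds = nfolds,
                                 seed = cv_seed)
    lambda <- sel$lambda
    alpha <- sel$alpha
  }
  B <- matrix(0, p, p, dimnames = list(order, order))
  SE <- matrix(NA_real_, p, p, dimnames = list(order, order))
  P <- matrix(NA_real_, p, p, dimnames = list(order, order))
  for (i in seq_len(p)[-1]) {
    pred <- seq_len(i - 1)
    Xi <- X[, pred, drop = FALSE]
    y <- X[, i]
    ols <- ols_on_predecessors(y, Xi)
    SE[i, pred] <- ols$se
    P[i, pred] <- ols$p
    if (lambda == 0) {
      B[i, pred] <- ols$coef
    } else {
      B[i, pred] <- enet_on_predecessors(y, Xi, lambda, alpha)
    }
  }
  structure(
    list(order = order, B = B, se = SE, p_value = P,
         significant = matrix(lower.tri(B), p, p, dimnames = dimnames(B)),
         lambda = lambda, alpha = alpha, n = n, filtered = FALSE),
    class = "lingam_fit"
  )
}

#' Cross-validated selection of the elasticnet penalty
#'
#' K-fold cross-validation of the summed squared prediction error over all
#' ordered regressions, on a `(lambda, alpha)` grid.  The chosen pair is
#' the smallest `lambda` whose total CV error is within one standard error
#' of the minimum (ties broken toward the minimizing `alpha`): shrinkage is
#' kept as small as the data allow so coefficient recovery stays nearly
#' unbiased.
#'
#' @param data Standardized tibble or matrix.
#' @param order Causal order.
#' @param lambda_grid,alpha_grid Candidate values; defaults
#'   `{0, 1e-4, 1e-3, 1e-2, 1e-1}` and `{0.1, 0.5, 0.9}`.
#' @param nfolds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `lambda`, `alpha`, and `cv_table` (a tibble of grid
#'   points with total CV error and SE).
#' @export
select_regularization <- function(data, order,
                                  lambda_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
                                  alpha_grid = c(0.1, 0.5, 0.9),
                                  nfolds = 5, seed = 1L) {
  X <- if (is.matrix(data)) data else as_index_matrix(data)
  X <- std_cols(X[, order, drop = FALSE])
  n <- nrow(X)
  p <- ncol(X)
  set.seed(derive_seed(seed, 3L))
  fold <- sample(rep_len(seq_len(nfolds), n))
  grid <- tidyr::expand_grid(lambda = sort(lambda_grid),
                             alpha = alpha_grid)
  err <- matrix(0, nrow(grid), nfolds)
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    te <- !tr
    for (g in seq_len(nrow(grid))) {
      tot <- 0
      for (i in seq_len(p)[-1]) {
        Xi_tr <- X[tr, seq_len(i - 1), drop = FALSE]
        y_tr <- X[tr, i]
        w <- if (grid$lambda[g] == 0) {
          ols_on_predecessors(y_tr, Xi_tr)$coef
        } else {
          enet_on_predecessors(y_tr, Xi_tr, grid$lambda[g], grid$alpha[g])
        }
        pred <- X[te, seq_len(i - 1), drop = FALSE] %*% w
        tot <- tot + mean((X[te, i] - pred)^2)
      }
      err[g, f] <- tot
    }
  }
  cv_table <- dplyr::mutate(grid,
    cv_error = rowMeans(err),
    cv_se = apply(err, 1, stats::sd) / sqrt(nfolds))
  best <- which.min(cv_table$cv_error)
  cutoff <- cv_table$cv_error[best] + cv_table$cv_se[best]
  ok <- cv_table$cv_error <= cutoff
  cand <- cv_table[ok, ]
  cand <- cand[base::order(cand$lambda,
                           abs(cand$alpha - cv_table$alpha[best])), ]
  list(lambda = cand$lambda[1], alpha = cand$alpha[1], cv_table = cv_table)
}

#' Prune edges by Bonferroni-corrected significance
#'
#' Per-edge p-values come from the unpenalized ordered regressions already
#' stored in the fit; an edge is kept iff its p-value is below
#' `alpha_level / N_tests`.  By default the family is the full set of
#' `p(p-1)/2` candidate edges (the edges of the diagram form one family);
#' `family = "per_regression"` instead corrects within each target's own
#' regression.  Coefficients are left untouched: only the `significant`
#' flags change.
#'
#' @param fit A `lingam_fit`.
#' @param alpha_level Family-wise error target (default 0.05).
#' @param family `"edges"` (default) or `"per_regression"`.
#' @return The updated `lingam_fit` with `filtered = TRUE`.
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 5000, seed = 1)
#' fit <- fit_b_matrix(generate_standardized(cfg), default_causal_order())
#' fit <- significance_filter(fit)
#' sum(fit$significant)
significance_filter <- function(fit, alpha_level = 0.05,
                                family = c("edges", "per_regression")) {
  stopifnot(inherits(fit, "lingam_fit"))
  family <- match.arg(family)
  p <- length(fit$order)
  keep <- matrix(FALSE, p, p, dimnames = dimnames(fit$B))
  if (family == "edges") {
    n_tests <- p * (p - 1) / 2
    keep[lower.tri(keep)] <-
      fit$p_value[lower.tri(keep)] < alpha_level / n_tests
  } else {
    for (i in seq_len(p)[-1]) {
      n_tests <- i - 1
      keep[i, 1:(i - 1)] <-
        fit$p_value[i, 1:(i - 1)] < alpha_level / n_tests
    }
  }
  fit$significant <- keep
  fit$alpha_level <- alpha_level
  fit$family <- family
  fit$filtered <- TRUE
  fit
}

#' One-call DirectLiNGAM estimate
#'
#' [estimate_order()] followed by [fit_b_matrix()] and
#' [significance_filter()].
#'
#' @inheritParams fit_b_matrix
#' @param alpha_level Significance level for edge pruning; `NULL` skips
#'   the filter.
#' @return A `lingam_fit`.
#' @export
direct_lingam <- function(data, lambda = 0, alpha = 0.5,
                          alpha_level = 0.05) {
  ord <- estimate_order(data)
  fit <- fit_b_matrix(data, ord, lambda = lambda, alpha = alpha)
  if (!is.null(alpha_level)) fit <- significance_filter(fit, alpha_level)
  fit
}

#' Extract one edge coefficient from a fit
#'
#' @param fit A `lingam_fit`.
#' @param source,target Index names.
#' @return The fitted coefficient of `source` on `target` (0 when `source`
#'   does not precede `target` in the fitted order).
#' @export
coef_edge <- function(fit, source, target) {
  stopifnot(inherits(fit, "lingam_fit"),
            source %in% fit$order, target %in% fit$order)
  unname(fit$B[target, source])
}

#' @export
print.lingam_fit <- function(x, ...) {
  cat("<lingam_fit> ", length(x$order), " indices, n = ", x$n, "\n",
      sep = "")
  cat("order:", paste(x$order, collapse = " -> "), "\n")
  cat("lambda =", x$lambda, " alpha =", x$alpha, "\n")
  if (isTRUE(x$filtered)) {
    cat("significant edges:", sum(x$significant), "of",
        sum(lower.tri(x$B)), sprintf("(Bonferroni, alpha = %g, %s family)\n",
                                     x$alpha_level, x$family))
  }
  invisible(x)
}

#' Tidy a fitted structural model into an edge table
#'
#' @param x A `lingam_fit`.
#' @param ... Unused.
#' @return A tibble with one row per candidate edge: `source`, `target`,
#'   `estimate`, `std_error`, `p_value`, `significant`.
#' @method tidy lingam_fit
#' @export
tidy.lingam_fit <- function(x, ...) {
  p <- length(x$order)
  rows <- which(lower.tri(x$B), arr.ind = TRUE)
  out <- tibble::tibble(
    source = x$order[rows[, "col"]],
    target = x$order[rows[, "row"]],
    estimate = x$B[rows],
    std_error = x$se[rows],
    p_value = x$p_value[rows],
    significant = x$significant[rows]
  )
  dplyr::arrange(out, match(.data$target, x$order),
                 match(.data$source, x$order))
}

#' One-row summary of a fitted structural model
#'
#' @param x A `lingam_fit`.
#' @param ... Unused.
#' @return A tibble with `n_obs`, `n_vars`, `n_edges`,
#'   `n_significant`, `lambda`, `alpha`.
#' @method glance lingam_fit
#' @export
glance.lingam_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n,
    n_vars = length(x$order),
    n_edges = sum(x$B != 0),
    n_significant = if (isTRUE(x$filtered)) sum(x$significant) else
      NA_integer_,
    lambda = x$lambda,
    alpha = x$alpha
  )
}
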