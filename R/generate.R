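#' Configuration of the synthetic checkup-data generator
#'
#' Describes a planted linear non-Gaussian acyclic structural model over a
#' set of named indices: a topological (causal) order, a structural
#' coefficient matrix on the standardized scale, a non-Gaussian disturbance
#' family per index, raw-unit marginal targets, and defect rates for the
#' raw-data emulation.  Variables are generated in causal order as
#' `x_i = sum_j B[i, j] x_j + e_i` with independent standardized
#' disturbances; disturbance variances are solved analytically so every
#' standardized variable has population variance exactly 1 (required
#' because the reference coefficients are on the standardized scale).
#'
#' @param order Character vector: index names in topological order.
#' @param b_matrix Numeric matrix with dimnames covering `order`; entry
#'   `(i, j)` is the coefficient of source `j` on target `i` and may be
#'   nonzero only when `j` precedes `i` in `order`.
#' @param n Number of records to generate (at least 2).
#' @param noise Named character vector (or single string, recycled) of
#'   disturbance families, each one of `"laplace"`, `"uniform"`,
#'   `"skewed-mixture"`.  Gaussian disturbances are rejected: the model is
#'   only identifiable with non-Gaussian disturbances.
#' @param marginals Data frame with columns `index`, `mean`, `sd` giving the
#'   raw-unit rescaling targets, or `NULL` to default to
#'   [checkup_marginals()] where available.
#' @param missing_rate,outlier_rate Expected fractions of cells (in `[0,
#'   0.5)`) turned into missing values / extreme outliers by
#'   [inject_defects()].
#' @param seed Master integer seed; all stages derive deterministic child
#'   seeds from it.
#'
#' @return An object of class `checkup_config`.
#' @seealso [default_checkup_config()], [generate_standardized()]
#' @export
#' @examples
#' cfg <- checkup_config(
#'   order = c("x1", "x2"),
#'   b_matrix = matrix(c(0, 0, 0.687, 0), 2, 2, byrow = TRUE,
#'                     dimnames = list(c("x1", "x2"), c("x1", "x2"))),
#'   n = 100, seed = 1
#' )
checkup_config <- function(order, b_matrix, n, noise = "laplace",
                           marginals = NULL, missing_rate = 0,
                           outlier_rate = 0, seed = 1L) {
  stopifnot(is.character(order), length(order) >= 1, !anyDuplicated(order))
  p <- length(order)
  if (is.null(dimnames(b_matrix))) {
    stopifnot(nrow(b_matrix) == p, ncol(b_matrix) == p)
    dimnames(b_matrix) <- list(order, order)
  }
  B <- b_matrix[order, order, drop = FALSE]
  if (any(B[upper.tri(B, diag = TRUE)] != 0)) {
    stop("b_matrix must be strictly lower triangular under `order`: ",
         "a coefficient points from a later to an earlier index",
         call. = FALSE)
  }
  if (length(noise) == 1 && is.null(names(noise))) {
    noise <- stats::setNames(rep(noise, p), order)
  }
  noise <- noise[order]
  bad <- !noise %in% c("laplace", "uniform", "skewed-mixture")
  if (any(is.na(noise)) || any(bad)) {
    stop("noise must be one of 'laplace', 'uniform', 'skewed-mixture' ",
         "for every index (Gaussian disturbances are not identifiable)",
         call. = FALSE)
  }
  if (is.null(marginals)) {
    marginals <- dplyr::filter(checkup_marginals(), .data$index %in% order)
    marginals <- dplyr::select(marginals, "index", "mean", "sd")
    if (nrow(marginals) < p) {
      extra <- tibble::tibble(index = setdiff(order, marginals$index),
                              mean = 0, sd = 1)
      marginals <- dplyr::bind_rows(marginals, extra)
    }
  }
  marginals <- tibble::as_tibble(marginals)[c("index", "mean", "sd")]
  stopifnot(all(order %in% marginals$index))
  if (any(marginals$sd <= 0)) {
    stop("marginal sd must be positive", call. = FALSE)
  }
  stopifnot(n >= 2, missing_rate >= 0, missing_rate < 0.5,
            outlier_rate >= 0, outlier_rate < 0.5)
  cfg <- structure(
    list(order = order, b_matrix = B, n = as.integer(n), noise = noise,
         marginals = marginals, missing_rate = missing_rate,
         outlier_rate = outlier_rate, seed = as.integer(seed)),
    class = "checkup_config"
  )
  # fails if the planted coefficients leave no room for a disturbance
  disturbance_sd(cfg)
  cfg
}

#' Default generator configuration: the reference 11-index model
#'
#' The shipped study conditions: the reference causal order
#' ([default_causal_order()]), the reference structural matrix
#' ([default_b_matrix()]), standardized Laplace disturbances for every
#' index, and the raw-unit marginals of [checkup_marginals()].
#'
#' @param n Sample size; defaults to 131036, the size of the reference
#'   population (women in their 70s).
#' @param seed Master seed.
#' @param noise Disturbance family specification; the default Laplace can be
#'   switched to `"skewed-mixture"` per index (TG and gGT are the natural
#'   candidates given their heavy right skew).
#' @param missing_rate,outlier_rate Defect rates for raw-data emulation.
#' @return A `checkup_config`.
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 500, seed = 7)
default_checkup_config <- function(n = 131036, seed = 1L, noise = "laplace",
                                   missing_rate = 0, outlier_rate = 0) {
  checkup_config(order = default_causal_order(),
                 b_matrix = default_b_matrix(), n = n, noise = noise,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 seed = seed)
}

#' @export
print.checkup_config <- function(x, ...) {
  cat("<checkup_config> ", length(x$order), " indices, n = ", x$n,
      ", seed = ", x$seed, "\n", sep = "")
  cat("order:", paste(x$order, collapse = " -> "), "\n")
  cat("nonzero coefficients:", sum(x$b_matrix != 0),
      "| noise:", paste(unique(x$noise), collapse = ", "), "\n")
  invisible(x)
}

# ---- disturbance machinery -------------------------------------------------

# Population covariance of the standardized variables, built recursively in
# topological order; used to solve each disturbance SD so Var(x_i) = 1.
disturbance_sd <- function(config) {
  B <- config$b_matrix
  p <- nrow(B)
  S <- diag(p)
  sds <- numeric(p)
  sds[1] <- 1
  if (p > 1) {
    for (i in 2:p) {
      b <- B[i, 1:(i - 1)]
      S[i, 1:(i - 1)] <- as.numeric(b %*% S[1:(i - 1), 1:(i - 1), drop = FALSE])
      S[1:(i - 1), i] <- S[i, 1:(i - 1)]
      parent_var <- sum(b * S[i, 1:(i - 1)])
      v <- 1 - parent_var
      if (v <= 0) {
        stop("planted coefficients for index '", config$order[i],
             "' imply parent variance >= 1; no valid disturbance exists",
             call. = FALSE)
      }
      sds[i] <- sqrt(v)
      S[i, i] <- 1
    }
  }
  stats::setNames(sds, config$order)
}

#' Population covariance of a planted standardized model
#'
#' Closed-form covariance of the standardized variables implied by a
#' generator configuration: `(I - B)^{-1} D (I - B)^{-T}`, with `D` the
#' diagonal matrix of disturbance variances.  All diagonal entries are 1 by
#' construction.  Serves as the analytic oracle against which generated
#' samples can be checked.
#'
#' @param config A [checkup_config()].
#' @return A p x p covariance (= correlation) matrix in causal-order
#'   coordinates.
#' @export
#' @examples
#' S <- planted_covariance(default_checkup_config(n = 10))
#' all.equal(unname(diag(S)), rep(1, 11))
planted_covariance <- function(config) {
  stopifnot(inherits(config, "checkup_config"))
  B <- config$b_matrix
  D <- diag(disturbance_sd(config)^2, nrow = nrow(B))
  A <- solve(diag(nrow(B)) - B)
  S <- A %*% D %*% t(A)
  dimnames(S) <- dimnames(B)
  S
}

# Standardized (mean 0, variance 1) non-Gaussian disturbance samples.
# laplace: scale 1/sqrt(2) (excess kurtosis +3)
# uniform: on [-sqrt(3), sqrt(3)] (excess kurtosis -1.2)
# skewed-mixture: two-component normal mixture, weight 0.85 / 0.15, the
#   minor component shifted right and widened, then standardized
#   analytically; right-skewed with positive excess kurtosis, mimicking the
#   heavy right tails of TG and gGT.
rnoise <- function(n, family) {
  switch(family,
    laplace = (rexp(n) - rexp(n)) / sqrt(2),
    uniform = runif(n, -sqrt(3), sqrt(3)),
    `skewed-mixture` = {
      w <- 0.15; m2 <- 2.2; s1 <- 0.7; s2 <- 1.6
      m1 <- -w * m2 / (1 - w)
      mixture_mean <- (1 - w) * m1 + w * m2            # 0 by construction
      mixture_var <- (1 - w) * (s1^2 + m1^2) + w * (s2^2 + m2^2) -
        mixture_mean^2
      comp <- runif(n) < w
      z <- ifelse(comp, rnorm(n, m2, s2), rnorm(n, m1, s1))
      (z - mixture_mean) / sqrt(mixture_var)
    },
    stop("unknown noise family: ", family, call. = FALSE)
  )
}

# ---- generation ------------------------------------------------------------

#' Generate a standardized synthetic checkup table
#'
#' Draws `config$n` records from the planted structural model: variables
#' are generated in topological order as the planted linear combination of
#' their parents plus an independent standardized non-Gaussian disturbance
#' scaled so each variable has population mean 0 and variance 1.
#'
#' @param config A [checkup_config()].
#' @return A tibble with an `id` column and one column per index, columns
#'   in canonical [checkup_indices()] order where applicable; carries
#'   attribute `standardized = TRUE`.
#' @export
#' @examples
#' tbl <- generate_standardized(default_checkup_config(n = 200, seed = 3))
#' round(colMeans(tbl[-1]), 1)
generate_standardized <- function(config) {
  stopifnot(inherits(config, "checkup_config"))
  n <- config$n
  p <- length(config$order)
  sds <- disturbance_sd(config)
  B <- config$b_matrix
  X <- matrix(0, n, p, dimnames = list(NULL, config$order))
  set.seed(derive_seed(config$seed, 1L))
  for (i in seq_len(p)) {
    e <- sds[i] * rnoise(n, config$noise[i])
    if (i > 1) {
      b <- B[i, 1:(i - 1)]
      nz <- which(b != 0)
      if (length(nz) > 0) {
        e <- e + X[, nz, drop = FALSE] %*% b[nz]
      }
    }
    X[, i] <- e
  }
  canonical <- intersect(checkup_indices(), config$order)
  col_order <- c(canonical, setdiff(config$order, canonical))
  out <- tibble::as_tibble(as.data.frame(X[, col_order, drop = FALSE]))
  out <- dplyr::bind_cols(tibble::tibble(id = seq_len(n)), out)
  attr(out, "standardized") <- TRUE
  out
}

#' Rescale a standardized table to raw clinical units
#'
#' Applies `mean + sd * x` per index using the configuration's marginal
#' targets, producing raw-unit columns whose sample mean and SD match the
#' targets up to sampling error.
#'
#' @param data Standardized checkup tibble (from [generate_standardized()]).
#' @param config The [checkup_config()] carrying the marginal targets.
#' @return The rescaled tibble, `standardized = FALSE`.
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 200, seed = 3)
#' raw <- rescale_to_units(generate_standardized(cfg), cfg)
#' round(mean(raw$HbA1c), 1)
rescale_to_units <- function(data, config) {
  stopifnot(inherits(config, "checkup_config"))
  marg <- config$marginals
  if (any(marg$sd <= 0)) stop("marginal sd must be positive", call. = FALSE)
  out <- data
  for (k in seq_len(nrow(marg))) {
    idx <- marg$index[k]
    if (idx %in% names(out)) {
      out[[idx]] <- marg$mean[k] + marg$sd[k] * out[[idx]]
    }
  }
  attr(out, "standardized") <- FALSE
  attr(out, "defect_log") <- attr(data, "defect_log")
  out
}

#' Inject missing cells and extreme outliers
#'
#' Emulates raw-data defects: each index cell is independently set missing
#' with probability `missing_rate`, and each remaining cell is replaced
#' with probability `outlier_rate` by a value beyond its column's
#' 0.05%/99.95% quantiles (random side).  Positions of every injected
#' defect are recorded in the `defect_log` attribute so cleaning can be
#' verified against ground truth.
#'
#' @param data Checkup tibble.
#' @param missing_rate,outlier_rate Cell-level defect probabilities in
#'   `[0, 0.5)`.
#' @param seed Integer seed.
#' @return The defected tibble with attribute `defect_log`, a list with
#'   tibbles `missing` (`row`, `index`) and `outliers` (`row`, `index`,
#'   `value`).
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 300, seed = 5)
#' bad <- inject_defects(generate_standardized(cfg), 0.01, 0.001, seed = 5)
#' nrow(attr(bad, "defect_log")$missing)
inject_defects <- function(data, missing_rate, outlier_rate, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 0.5,
            outlier_rate >= 0, outlier_rate < 0.5)
  idx_cols <- intersect(names(data), setdiff(names(data), "id"))
  out <- data
  n <- nrow(out)
  miss_log <- list()
  out_log <- list()
  set.seed(derive_seed(seed, 2L))
  for (col in idx_cols) {
    x <- out[[col]]
    miss <- which(runif(n) < missing_rate)
    if (length(miss) > 0) {
      x[miss] <- NA_real_
      miss_log[[col]] <- tibble::tibble(row = miss, index = col)
    }
    candidates <- setdiff(which(runif(n) < outlier_rate), miss)
    if (length(candidates) > 0) {
      q <- quantile(out[[col]], c(0.0005, 0.9995), na.rm = TRUE, names = FALSE)
      span <- max(q[2] - q[1], 1e-8)
      side <- runif(length(candidates)) < 0.5
      mag <- span * (0.05 + rexp(length(candidates), rate = 10))
      val <- ifelse(side, q[1] - mag, q[2] + mag)
      x[candidates] <- val
      out_log[[col]] <- tibble::tibble(row = candidates, index = col,
                                       value = val)
    }
    out[[col]] <- x
  }
  attr(out, "defect_log") <- list(
    missing = if (length(miss_log)) dplyr::bind_rows(miss_log) else
      tibble::tibble(row = integer(), index = character()),
    outliers = if (length(out_log)) dplyr::bind_rows(out_log) else
      tibble::tibble(row = integer(), index = character(), value = double())
  )
  attr(out, "standardized") <- attr(data, "standardized")
  out
}

#' Recode sentinel values to missing
#'
#' Raw checkup extracts sometimes encode data-entry mistakes as impossible
#' sentinel codes rather than empty cells.  The sentinel list is
#' user-configurable because no fixed set exists.
#'
#' @param data Checkup tibble.
#' @param sentinels Numeric vector of values to recode to `NA` in every
#'   index column.
#' @return The recoded tibble.
#' @export
recode_sentinels <- function(data, sentinels) {
  if (length(sentinels) == 0) return(data)
  out <- data
  for (col in setdiff(names(out), "id")) {
    if (is.numeric(out[[col]])) {
      out[[col]][out[[col]] %in% sentinels] <- NA_real_
    }
  }
  out
}

# ---- file interfaces -------------------------------------------------------

#' Read / write checkup CSV
#'
#' CSV dialect used by all interfaces: a header row with `id` then the
#' index names (gamma-GT as `gGT`); missing values as empty fields.
#'
#' @param data Checkup tibble.
#' @param path File path.
#' @return `write_checkup_csv()` returns `path` invisibly;
#'   `read_checkup_csv()` returns a tibble.
#' @export
write_checkup_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' @rdname write_checkup_csv
#' @export
read_checkup_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
}

#' Serialize / load a generator configuration as JSON
#'
#' @param config A [checkup_config()].
#' @param path File path.
#' @return `write_checkup_config()` returns `path` invisibly;
#'   `read_checkup_config()` returns the `checkup_config`.
#' @export
write_checkup_config <- function(config, path) {
  stopifnot(inherits(config, "checkup_config"))
  obj <- list(
    order = config$order,
    b_matrix = unclass(config$b_matrix),
    noise = as.list(config$noise),
    marginals = config$marginals,
    n = config$n,
    missing_rate = config$missing_rate,
    outlier_rate = config$outlier_rate,
    seed = config$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_checkup_config
#' @export
read_checkup_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  B <- as.matrix(obj$b_matrix)
  dimnames(B) <- list(obj$order, obj$order)
  checkup_config(order = obj$order, b_matrix = B, n = obj$n,
                 noise = unlist(obj$noise),
                 marginals = tibble::as_tibble(obj$marginals),
                 missing_rate = obj$missing_rate,
                 outlier_rate = obj$outlier_rate, seed = obj$seed)
}
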