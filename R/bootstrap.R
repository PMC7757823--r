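#' Resample records with replacement
#'
#' Classical bootstrap resample: `n` rows drawn i.i.d. uniformly with
#' replacement from the `n` input rows.
#'
#' @param data Checkup tibble.
#' @param seed Integer seed; identical seeds give identical resamples.
#' @return A tibble of the same shape.
#' @export
resample_rows <- function(data, seed = 1L) {
  n <- nrow(data)
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, 4L))
  data[sample.int(n, n, replace = TRUE), , drop = FALSE]
}

order_key <- function(ord) paste(ord, collapse = " ")

#' Bootstrap the full DirectLiNGAM estimate
#'
#' For each replicate: resample records with replacement, re-standardize,
#' estimate the causal order, and fit the structural matrix under that
#' order.  Replicates are aggregated into (a) a ranked frequency table of
#' estimated orders and (b) per-edge coefficient means/SDs over the
#' replicates whose order equals the modal (most frequent) order — the
#' conditional summary a coefficient table reports.  An unconditional
#' per-edge summary (over every replicate in which the edge was a
#' candidate, i.e. source preceded target) is also returned.
#'
#' All replicate seeds derive deterministically from `seed`; a failing
#' replicate is logged and excluded, with the count reported.
#'
#' @param data Cleaned, standardized checkup tibble.
#' @param n_reps Number of bootstrap replicates (reference analyses use
#'   1000; smaller runs should record the reduction).
#' @param seed Master seed.
#' @param lambda,alpha Elasticnet setting reused for every replicate (fit
#'   once on the full data to choose it, or leave the near-unpenalized
#'   default).
#' @return A `lingam_boot`: list with `n_reps`, `order_counts` (tibble:
#'   `order`, `count`, plus one column per causal position), `modal_order`,
#'   `coef_stats` (conditional on the modal order: `source`, `target`,
#'   `mean`, `sd`, `n`), `coef_stats_unconditional`, `n_failed`, `seed`.
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 2000, seed = 1)
#' boot <- bootstrap_lingam(generate_standardized(cfg), n_reps = 5, seed = 1)
#' boot$order_counts
bootstrap_lingam <- function(data, n_reps = 1000, seed = 1L,
                             lambda = 0, alpha = 0.5) {
  stopifnot(n_reps >= 1)
  X <- if (is.matrix(data)) data else as_index_matrix(data)
  if (anyNA(X)) stop("bootstrap_lingam(): missing values; clean first",
                     call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  vars <- colnames(X)
  orders <- character(n_reps)
  Bs <- array(NA_real_, c(n_reps, p, p), dimnames = list(NULL, vars, vars))
  failed <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, 1000L + r)
    res <- tryCatch({
      set.seed(rep_seed)
      Xr <- std_cols(X[sample.int(n, n, replace = TRUE), , drop = FALSE])
      ord <- estimate_order(Xr)
      fit <- fit_b_matrix(Xr, ord, lambda = lambda, alpha = alpha)
      list(ord = ord, B = fit$B)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      orders[r] <- NA_character_
      next
    }
    orders[r] <- order_key(res$ord)
    # store in canonical variable coordinates: [target, source]
    Bs[r, res$ord, res$ord] <- res$B
  }
  ok <- !is.na(orders)
  counts <- sort(table(orders[ok]), decreasing = TRUE)
  order_counts <- tibble::tibble(order = names(counts),
                                 count = as.integer(counts))
  pos <- do.call(rbind, strsplit(order_counts$order, " ", fixed = TRUE))
  if (!is.null(pos)) {
    colnames(pos) <- paste0("pos", seq_len(p))
    order_counts <- dplyr::bind_cols(order_counts,
                                     tibble::as_tibble(as.data.frame(pos)))
  }
  modal <- if (nrow(order_counts) > 0) order_counts$order[1] else
    NA_character_
  modal_ord <- if (!is.na(modal)) strsplit(modal, " ", fixed = TRUE)[[1]]
    else character()

  edge_stats <- function(rep_idx) {
    if (length(rep_idx) == 0 || length(modal_ord) < 2) {
      return(tibble::tibble(source = character(), target = character(),
                            mean = double(), sd = double(), n = integer()))
    }
    pairs <- which(lower.tri(diag(p)), arr.ind = TRUE)
    purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
      tgt <- modal_ord[pairs[k, "row"]]
      src <- modal_ord[pairs[k, "col"]]
      v <- Bs[rep_idx, tgt, src]
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NULL)
      tibble::tibble(source = src, target = tgt, mean = mean(v),
                     sd = if (length(v) > 1) stats::sd(v) else 0,
                     n = length(v))
    })
  }
  modal_idx <- which(orders == modal)
  structure(
    list(n_reps = n_reps, order_counts = order_counts,
         modal_order = modal_ord,
         modal_count = if (nrow(order_counts) > 0)
           order_counts$count[1] else 0L,
         coef_stats = edge_stats(modal_idx),
         coef_stats_unconditional = edge_stats(which(ok)),
         n_failed = failed, seed = as.integer(seed),
         lambda = lambda, alpha = alpha, n = n),
    class = "lingam_boot"
  )
}

#' Modal-order stability as a function of sample size
#'
#' For each requested size, draws one subsample without replacement from
#' the full table, then runs [bootstrap_lingam()] within it and records
#' how often the modal causal order is hit.  Smaller samples yield less
#' dominant modal orders: the curve quantifies how many records an
#' ordering needs to be trustworthy.
#'
#' @param data Cleaned, standardized checkup tibble.
#' @param sample_sizes Integer vector of subsample sizes, each at most
#'   `nrow(data)`; a size equal to `nrow(data)` uses the full table.
#' @param n_reps Bootstrap replicates per size.
#' @param seed Master seed.
#' @param lambda,alpha Passed to [bootstrap_lingam()].
#' @return A tibble: `sample_size`, `modal_order`, `modal_count`,
#'   `modal_frequency` (count / n_reps), `n_reps`.
#' @export
order_stability_curve <- function(data, sample_sizes, n_reps = 1000,
                                  seed = 1L, lambda = 0, alpha = 0.5) {
  X <- if (is.matrix(data)) data else as_index_matrix(data)
  n <- nrow(X)
  if (any(sample_sizes > n)) {
    stop("order_stability_curve(): sample size exceeds available records",
         call. = FALSE)
  }
  purrr::map_dfr(seq_along(sample_sizes), function(k) {
    size <- sample_sizes[k]
    if (size < n) {
      set.seed(derive_seed(seed, 5000L + k))
      sub <- X[sample.int(n, size, replace = FALSE), , drop = FALSE]
    } else {
      sub <- X
    }
    boot <- bootstrap_lingam(sub, n_reps = n_reps,
                             seed = derive_seed(seed, 6000L + k),
                             lambda = lambda, alpha = alpha)
    tibble::tibble(sample_size = as.integer(size),
                   modal_order = order_key(boot$modal_order),
                   modal_count = boot$modal_count,
                   modal_frequency = boot$modal_count / n_reps,
                   n_reps = as.integer(n_reps))
  })
}

#' @export
print.lingam_boot <- function(x, ...) {
  cat("<lingam_boot> ", x$n_reps, " replicates, n = ", x$n, "\n", sep = "")
  cat("modal order (", x$modal_count, "/", x$n_reps, "): ",
      paste(x$modal_order, collapse = " -> "), "\n", sep = "")
  if (x$n_failed > 0) cat("failed replicates:", x$n_failed, "\n")
  invisible(x)
}

#' Tidy a bootstrap summary into a per-edge table
#'
#' @param x A `lingam_boot`.
#' @param conditional If `TRUE` (default) the modal-order-conditional
#'   coefficient summary; otherwise the unconditional one.
#' @param ... Unused.
#' @return Tibble `source`, `target`, `mean`, `sd`, `n`.
#' @method tidy lingam_boot
#' @export
tidy.lingam_boot <- function(x, conditional = TRUE, ...) {
  if (conditional) x$coef_stats else x$coef_stats_unconditional
}

#' One-row summary of a bootstrap run
#'
#' @param x A `lingam_boot`.
#' @param ... Unused.
#' @return Tibble with `n_reps`, `n_obs`, `n_orders`, `modal_count`,
#'   `modal_frequency`, `n_failed`.
#' @method glance lingam_boot
#' @export
glance.lingam_boot <- function(x, ...) {
  tibble::tibble(
    n_reps = x$n_reps, n_obs = x$n,
    n_orders = nrow(x$order_counts),
    modal_count = x$modal_count,
    modal_frequency = x$modal_count / x$n_reps,
    n_failed = x$n_failed
  )
}

#' Write the ranked order-frequency table as CSV
#'
#' One row per distinct estimated order: a `count` column then one column
#' per causal position, most frequent order first.
#'
#' @param boot A `lingam_boot`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_order_counts <- function(boot, path) {
  stopifnot(inherits(boot, "lingam_boot"))
  out <- dplyr::select(boot$order_counts, -"order")
  readr::write_csv(out, path)
  invisible(path)
}

#' Bar chart of bootstrap order frequencies
#'
#' @param object A `lingam_boot`.
#' @param max_orders Show at most this many distinct orders.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lingam_boot
#' @export
autoplot.lingam_boot <- function(object, max_orders = 10, ...) {
  df <- head(object$order_counts, max_orders)
  df$order <- factor(df$order, levels = rev(df$order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$order)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = sprintf("frequency in %d replicates", object$n_reps),
                  y = NULL, title = "Bootstrap causal-order frequencies") +
    ggplot2::theme_minimal()
}

#' Line plot of an order-stability curve
#'
#' @param curve Tibble from [order_stability_curve()].
#' @return A ggplot of modal-order frequency against sample size.
#' @export
plot_stability_curve <- function(curve) {
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$sample_size,
                               y = .data$modal_frequency)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "sample size", y = "modal-order frequency",
                  title = "Causal-order stability vs sample size") +
    ggplot2::theme_minimal()
}
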