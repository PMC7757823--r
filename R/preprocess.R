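#' Drop records with any missing index value
#'
#' First cleaning stage: a record (row) is kept only if every index column
#' is observed.  Row order is preserved.
#'
#' @param data Checkup tibble; an `id` column, if present, is ignored by
#'   the completeness check.
#' @return The complete-case tibble.
#' @export
#' @examples
#' tbl <- tibble::tibble(id = 1:3, a = c(1, NA, 3), b = c(1, 2, 3))
#' drop_incomplete(tbl)
drop_incomplete <- function(data) {
  idx <- setdiff(names(data), "id")
  keep <- stats::complete.cases(as.data.frame(data)[idx])
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    message("drop_incomplete(): no complete records remain")
  }
  attr(out, "standardized") <- attr(data, "standardized")
  out
}

#' Trim per-index extremes
#'
#' Second cleaning stage: for each index, the `floor(n * frac_per_side)`
#' smallest and largest observations are flagged, and every record flagged
#' by at least one index is removed (whole records, matching the practice
#' of removing extreme IDs).  The reported bounds are the most extreme
#' retained values per index; observations exactly equal to a bound are
#' retained, so duplicated boundary values are never over-trimmed.
#' Bounds are computed once on the input table, not iteratively.
#'
#' @param data Complete-case checkup tibble (run [drop_incomplete()]
#'   first).
#' @param frac_per_side Fraction trimmed from each tail of each index, in
#'   `[0, 0.5)`; default `5e-4` (0.05% per side).
#' @return The trimmed tibble, carrying a `cleaning_report` attribute (see
#'   [cleaning_report()]).  Surviving values are never modified.
#' @export
#' @examples
#' tbl <- tibble::tibble(x = c(rnorm(100), 50))
#' nrow(trim_outliers(tbl, frac_per_side = 0.01))
trim_outliers <- function(data, frac_per_side = 5e-4) {
  stopifnot(frac_per_side >= 0, frac_per_side < 0.5)
  idx <- setdiff(names(data), "id")
  n <- nrow(data)
  k <- floor(n * frac_per_side)
  drop_row <- rep(FALSE, n)
  per_index <- vector("list", length(idx))
  names(per_index) <- idx
  for (col in idx) {
    x <- data[[col]]
    if (anyNA(x) || !all(is.finite(x))) {
      stop("trim_outliers(): non-finite values in '", col,
           "'; run drop_incomplete() first", call. = FALSE)
    }
    xs <- sort(x)
    low <- xs[k + 1]           # smallest retained value
    high <- xs[n - k]          # largest retained value
    rm_low <- x < low
    rm_high <- x > high
    drop_row <- drop_row | rm_low | rm_high
    per_index[[col]] <- tibble::tibble(
      index = col, low = low, high = high,
      removed_low = sum(rm_low), removed_high = sum(rm_high)
    )
  }
  out <- data[!drop_row, , drop = FALSE]
  report <- structure(
    list(n_input = n, n_after_na = n, n_after_trim = nrow(out),
         frac_per_side = frac_per_side,
         bounds = dplyr::bind_rows(per_index)),
    class = "cleaning_report"
  )
  attr(out, "cleaning_report") <- report
  attr(out, "standardized") <- attr(data, "standardized")
  out
}

#' Standardize index columns
#'
#' Final cleaning stage: every index column is centered and scaled to
#' sample mean 0 and sample SD 1 (n - 1 denominator).  The per-index
#' (mean, sd) pairs are retained in the `scaling` attribute for inverse
#' transforms.  Pairwise sample correlations are unchanged.
#'
#' @param data Checkup tibble with numeric index columns of positive SD.
#' @return Standardized tibble with attributes `standardized = TRUE` and
#'   `scaling` (tibble `index`, `mean`, `sd`).
#' @export
#' @examples
#' std <- standardize_indices(tibble::tibble(x = c(1, 2, 3)))
#' c(mean(std$x), sd(std$x))
standardize_indices <- function(data) {
  idx <- setdiff(names(data), "id")
  out <- data
  scaling <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    x <- data[[idx[j]]]
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      stop("standardize_indices(): column '", idx[j],
           "' is constant or degenerate", call. = FALSE)
    }
    out[[idx[j]]] <- (x - m) / s
    scaling[[j]] <- tibble::tibble(index = idx[j], mean = m, sd = s)
  }
  attr(out, "scaling") <- dplyr::bind_rows(scaling)
  attr(out, "standardized") <- TRUE
  attr(out, "cleaning_report") <- attr(data, "cleaning_report")
  out
}

#' Run the full cleaning pipeline
#'
#' Fixed order: [drop_incomplete()] then [trim_outliers()] then
#' [standardize_indices()].
#'
#' @param data Raw checkup tibble.
#' @param frac_per_side Trim fraction per side, default 0.05%.
#' @param sentinels Optional numeric sentinel codes recoded to missing
#'   before the completeness check.
#' @return Cleaned, standardized tibble with a full [cleaning_report()]
#'   attribute.
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 500, seed = 2)
#' raw <- rescale_to_units(generate_standardized(cfg), cfg)
#' cleaned <- clean_checkup(raw)
#' cleaning_report(cleaned)
clean_checkup <- function(data, frac_per_side = 5e-4, sentinels = NULL) {
  n_input <- nrow(data)
  if (!is.null(sentinels)) data <- recode_sentinels(data, sentinels)
  complete <- drop_incomplete(data)
  trimmed <- trim_outliers(complete, frac_per_side = frac_per_side)
  report <- attr(trimmed, "cleaning_report")
  report$n_input <- n_input
  report$n_after_na <- nrow(complete)
  out <- standardize_indices(trimmed)
  attr(out, "cleaning_report") <- report
  out
}

#' Retrieve the cleaning report of a cleaned table
#'
#' @param data A tibble returned by [trim_outliers()] or [clean_checkup()].
#' @return The `cleaning_report` object (or `NULL`): input/after-NA/after-
#'   trim record counts and per-index trim bounds with removal counts.
#' @export
cleaning_report <- function(data) {
  attr(data, "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat("  records in:        ", x$n_input, "\n")
  cat("  after NA removal:  ", x$n_after_na, "\n")
  cat("  after trimming:    ", x$n_after_trim,
      sprintf("  (%.2f%%/side)\n", 100 * x$frac_per_side))
  print(x$bounds, n = Inf)
  invisible(x)
}

#' Export a cleaning report as JSON
#'
#' @param report A `cleaning_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "cleaning_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
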