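#' Color bin of a diagram edge
#'
#' Maps a standardized coefficient to one of six rainbow-order colors:
#' red for `b >= 0.1`, orange for `0.1 > b >= 0.05`, yellow for
#' `0.05 > b > 0`, sky blue for `0 > b >= -0.05`, blue for
#' `-0.05 > b >= -0.1`, deep blue for `b < -0.1`.  Warm colors mean the
#' target rises with the source, cool colors that it falls.  The bins
#' partition the nonzero reals; `b = 0` has no color (no edge is drawn at
#' exactly zero).
#'
#' @param b Numeric vector of coefficients (finite).
#' @return Character vector of color names (`"red"`, `"orange"`,
#'   `"yellow"`, `"skyblue"`, `"blue"`, `"deepblue"`); `NA` for `b = 0`.
#' @export
#' @examples
#' color_bin(c(0.687, 0.06, -0.03, -0.2))
color_bin <- function(b) {
  stopifnot(is.numeric(b), all(is.finite(b)))
  dplyr::case_when(
    b >= 0.1 ~ "red",
    b >= 0.05 ~ "orange",
    b > 0 ~ "yellow",
    b == 0 ~ NA_character_,
    b >= -0.05 ~ "skyblue",
    b >= -0.1 ~ "blue",
    TRUE ~ "deepblue"
  )
}

#' Width of a diagram edge
#'
#' Affine in `log |b|`:
#' `w = w_min + (w_max - w_min) (log|b| - log b_floor) /
#' (log b_ceil - log b_floor)`, clipped to `[w_min, w_max]`; monotone in
#' `|b|` and independent of sign, so equally strong positive and negative
#' effects draw equally thick.
#'
#' @param b Nonzero coefficient(s).
#' @param w_min,w_max Width range (default 0.5 to 5).
#' @param b_floor,b_ceil Coefficient magnitudes mapped to `w_min` /
#'   `w_max` (defaults 0.01 and 1).
#' @return Numeric width(s).
#' @export
#' @examples
#' edge_width(c(0.687, -0.687, 0.05))
edge_width <- function(b, w_min = 0.5, w_max = 5, b_floor = 0.01,
                       b_ceil = 1) {
  stopifnot(all(b != 0), all(is.finite(b)), w_max >= w_min,
            b_ceil > b_floor, b_floor > 0)
  f <- (log(abs(b)) - log(b_floor)) / (log(b_ceil) - log(b_floor))
  w_min + (w_max - w_min) * pmin(pmax(f, 0), 1)
}

#' Build a diagram specification from a fitted model
#'
#' Collects the drawable edges of a (significance-filtered) structural
#' model: each kept edge with `|b|` above `threshold` gets its color bin
#' and width; each node's radius is the sum of absolute coefficients of
#' its kept incident edges (in and out), so heavily connected indices draw
#' larger.
#'
#' @param fit A `lingam_fit`, normally after [significance_filter()].
#' @param threshold Minimum `|b|` for an edge to be drawn; 0 draws every
#'   significant edge, 0.1 keeps only the strong ones.
#' @param only_significant Drop edges flagged insignificant (default
#'   `TRUE`; ignored when the fit was never filtered).
#' @return A `diagram_spec`: list of tibbles `nodes` (`index`, `radius`)
#'   and `edges` (`source`, `target`, `b`, `color`, `width`).
#' @export
#' @examples
#' cfg <- default_checkup_config(n = 5000, seed = 1)
#' fit <- direct_lingam(generate_standardized(cfg))
#' diagram_spec(fit, threshold = 0.1)
diagram_spec <- function(fit, threshold = 0, only_significant = TRUE) {
  stopifnot(inherits(fit, "lingam_fit"), threshold >= 0)
  edges <- tidy(fit)
  if (only_significant && isTRUE(fit$filtered)) {
    edges <- dplyr::filter(edges, .data$significant)
  }
  edges <- dplyr::filter(edges, abs(.data$estimate) > threshold,
                         .data$estimate != 0)
  edges <- dplyr::transmute(edges,
    source = .data$source, target = .data$target, b = .data$estimate,
    color = color_bin(.data$estimate), width = edge_width(.data$b))
  radius <- purrr::map_dbl(fit$order, function(v) {
    sum(abs(edges$b[edges$source == v | edges$target == v]))
  })
  structure(
    list(nodes = tibble::tibble(index = fit$order, radius = radius),
         edges = edges, threshold = threshold),
    class = "diagram_spec"
  )
}

#' @export
print.diagram_spec <- function(x, ...) {
  cat("<diagram_spec> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|b| > ", x$threshold, ")\n", sep = "")
  print(x$edges, n = 20)
  invisible(x)
}

#' Export a causal diagram as DOT and edge-list CSV
#'
#' Writes a Graphviz DOT file (nodes sized by radius, edges colored and
#' weighted per [color_bin()] / [edge_width()]) and a CSV of the edge list
#' (`source`, `target`, `b`, `color`, `width`).  Output is deterministic:
#' nodes in causal order, edges ordered by target then source.
#'
#' @param fit A `lingam_fit` (normally significance-filtered).
#' @param dot_path,csv_path Output paths (`NULL` skips either file).
#' @param threshold Minimum `|b|`, as in [diagram_spec()].
#' @return The `diagram_spec`, invisibly.
#' @export
export_diagram <- function(fit, dot_path = NULL, csv_path = NULL,
                           threshold = 0) {
  spec <- diagram_spec(fit, threshold = threshold)
  if (!is.null(csv_path)) {
    readr::write_csv(spec$edges, csv_path)
  }
  if (!is.null(dot_path)) {
    dot_colors <- c(red = "red", orange = "orange", yellow = "gold",
                    skyblue = "skyblue", blue = "blue",
                    deepblue = "navy")
    lines <- c("digraph causal {", "  rankdir=LR;",
               "  node [shape=circle, style=filled, fillcolor=white];")
    for (k in seq_len(nrow(spec$nodes))) {
      lines <- c(lines, sprintf('  "%s" [width=%.3f];',
                                spec$nodes$index[k],
                                0.5 + 0.5 * spec$nodes$radius[k]))
    }
    for (k in seq_len(nrow(spec$edges))) {
      e <- spec$edges[k, ]
      lines <- c(lines, sprintf(
        '  "%s" -> "%s" [color=%s, penwidth=%.3f, label="%.3f"];',
        e$source, e$target, dot_colors[[e$color]], e$width, e$b))
    }
    lines <- c(lines, "}")
    writeLines(lines, dot_path)
  }
  invisible(spec)
}

#' Plot a causal diagram
#'
#' Circular-layout ggplot of a [diagram_spec()]: nodes on a circle sized
#' by radius, directed edges drawn with the diagram's color and width
#' encoding.
#'
#' @param object A `diagram_spec`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diagram_spec
#' @export
autoplot.diagram_spec <- function(object, ...) {
  nodes <- object$nodes
  p <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = p + 1)[seq_len(p)]
  nodes$x <- cos(theta)
  nodes$y <- sin(theta)
  edges <- dplyr::left_join(object$edges,
                            dplyr::select(nodes, source = "index",
                                          x0 = "x", y0 = "y"),
                            by = "source")
  edges <- dplyr::left_join(edges,
                            dplyr::select(nodes, target = "index",
                                          x1 = "x", y1 = "y"),
                            by = "target")
  palette <- c(red = "#d7191c", orange = "#fdae61", yellow = "#e6c700",
               skyblue = "#74b9d8", blue = "#2c7bb6", deepblue = "#08306b")
  gg <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    gg <- gg + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, color = .data$color,
                   linewidth = .data$width),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.18, "inches"),
                             type = "closed"),
      alpha = 0.85, lineend = "round") +
      ggplot2::scale_color_manual(values = palette, guide = "none") +
      ggplot2::scale_linewidth_identity()
  }
  gg +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$radius),
                        color = "grey30", fill = "white", shape = 21) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$index)) +
    ggplot2::scale_size_continuous(range = c(3, 12), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void()
}

#' Percentile summary of a raw-unit checkup table
#'
#' Per-index minimum, quartiles, maximum, mean and SD — the standard
#' marginal summary for a raw (unstandardized) table.
#'
#' @param data Raw-unit checkup tibble (an `id` column is ignored).
#' @return A tibble: `index`, `min`, `q25`, `q50`, `q75`, `max`, `mean`,
#'   `sd`.
#' @export
#' @examples
#' summarize_percentiles(tibble::tibble(x = c(1, 2, 3, 4)))
summarize_percentiles <- function(data) {
  idx <- setdiff(names(data), "id")
  if (nrow(data) == 0 || length(idx) == 0) {
    stop("summarize_percentiles(): empty table", call. = FALSE)
  }
  purrr::map_dfr(idx, function(col) {
    x <- data[[col]]
    q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE, names = FALSE)
    tibble::tibble(index = col, min = q[1], q25 = q[2], q50 = q[3],
                   q75 = q[4], max = q[5], mean = mean(x, na.rm = TRUE),
                   sd = stats::sd(x[!is.na(x)]))
  })
}
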