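test_that("color bins reproduce the six-color encoding at each boundary", {
  eps <- 1e-12
  expect_identical(color_bin(0.687), "red")
  expect_identical(color_bin(0.06), "orange")
  expect_identical(color_bin(-0.03), "skyblue")
  # boundaries and their eps-neighbourhoods
  expect_identical(color_bin(c(0.1, 0.1 + eps, 0.1 - eps)),
                   c("red", "red", "orange"))
  expect_identical(color_bin(c(0.05, 0.05 + eps, 0.05 - eps)),
                   c("orange", "orange", "yellow"))
  expect_identical(color_bin(c(eps, -eps)), c("yellow", "skyblue"))
  expect_identical(color_bin(c(-0.05, -0.05 + eps, -0.05 - eps)),
                   c("skyblue", "skyblue", "blue"))
  expect_identical(color_bin(c(-0.1, -0.1 + eps, -0.1 - eps)),
                   c("blue", "blue", "deepblue"))
  expect_identical(color_bin(-0.2), "deepblue")
  # zero draws no edge, everything else exactly one bin
  expect_true(is.na(color_bin(0)))
  set.seed(25)
  b <- runif(200, -0.5, 0.5)
  b <- b[b != 0]
  expect_false(anyNA(color_bin(b)))
  expect_error(color_bin(Inf))
})

test_that("edge width is monotone in |b|, sign-blind and clipped", {
  expect_gte(edge_width(0.3), edge_width(0.2))
  expect_identical(edge_width(0.3), edge_width(-0.3))
  expect_identical(edge_width(1e-6), 0.5)    # clipped at w_min
  expect_identical(edge_width(10), 5)        # clipped at w_max
  # width is bin-independent: continuous across the 0.1 color boundary
  expect_equal(edge_width(0.1), edge_width(0.1 + 1e-12), tolerance = 1e-9)
  expect_error(edge_width(0))
})

test_that("diagram edges at threshold 0.1 come from strong planted edges", {
  cfg <- default_checkup_config(n = 20000, seed = 26)
  tbl <- generate_standardized(cfg)
  fit <- significance_filter(fit_b_matrix(tbl, default_causal_order()))
  spec <- diagram_spec(fit, threshold = 0.1)
  planted <- default_b_matrix()
  for (k in seq_len(nrow(spec$edges))) {
    expect_gt(abs(planted[spec$edges$target[k], spec$edges$source[k]]),
              0.08)   # near/above the drawing threshold
  }
  # the strong HDL links are drawn
  key <- paste(spec$edges$source, spec$edges$target)
  expect_true("HDL TG" %in% key)
  expect_true("HDL BMI" %in% key)
  # node radius equals the sum of |b| over kept incident edges
  hdl <- spec$nodes$radius[spec$nodes$index == "HDL"]
  expect_equal(hdl, sum(abs(spec$edges$b[spec$edges$source == "HDL" |
                                           spec$edges$target == "HDL"])))
})

test_that("export writes deterministic DOT and CSV artifacts", {
  cfg <- chain3_config(n = 3000, seed = 27, b21 = 0.7, b32 = 0.5)
  tbl <- generate_standardized(cfg)
  fit <- significance_filter(fit_b_matrix(tbl, c("x1", "x2", "x3")))
  dot1 <- withr::local_tempfile(fileext = ".dot")
  csv1 <- withr::local_tempfile(fileext = ".csv")
  export_diagram(fit, dot_path = dot1, csv_path = csv1)
  dot2 <- withr::local_tempfile(fileext = ".dot")
  csv2 <- withr::local_tempfile(fileext = ".csv")
  export_diagram(fit, dot_path = dot2, csv_path = csv2)
  expect_identical(readLines(dot1), readLines(dot2))
  expect_identical(readLines(csv1), readLines(csv2))
  edges <- readr::read_csv(csv1, show_col_types = FALSE)
  expect_named(edges, c("source", "target", "b", "color", "width"))
  expect_true(any(grepl("->", readLines(dot1), fixed = TRUE)))
  # edges respect the causal direction of the fitted order
  pos <- match(edges$source, fit$order)
  expect_true(all(pos < match(edges$target, fit$order)))
})

test_that("an edgeless model exports header-only outputs", {
  nm <- c("a", "b")
  cfg <- checkup_config(nm, matrix(0, 2, 2, dimnames = list(nm, nm)),
                        n = 2000, seed = 28)
  fit <- significance_filter(
    fit_b_matrix(generate_standardized(cfg), nm))
  dot <- withr::local_tempfile(fileext = ".dot")
  csv <- withr::local_tempfile(fileext = ".csv")
  spec <- export_diagram(fit, dot_path = dot, csv_path = csv,
                         threshold = 0.1)
  expect_identical(nrow(spec$edges), 0L)
  expect_identical(readLines(csv), "source,target,b,color,width")
  expect_false(any(grepl("->", readLines(dot), fixed = TRUE)))
})

test_that("percentile summaries are ordered and hit marginal targets", {
  s <- summarize_percentiles(tibble::tibble(x = c(1, 2, 3, 4)))
  expect_identical(s$min, 1)
  expect_identical(s$q50, 2.5)
  expect_identical(s$max, 4)
  cfg <- default_checkup_config(n = 20000, seed = 29)
  raw <- rescale_to_units(generate_standardized(cfg), cfg)
  tab <- summarize_percentiles(raw)
  hba1c <- tab[tab$index == "HbA1c", ]
  expect_equal(hba1c$mean, 5.72, tolerance = 0.03)
  expect_equal(hba1c$sd, 0.63, tolerance = 0.03)
  expect_true(all(tab$min <= tab$q25 & tab$q25 <= tab$q50 &
                    tab$q50 <= tab$q75 & tab$q75 <= tab$max))
  expect_error(summarize_percentiles(tibble::tibble()), "empty")
})

test_that("plot builders return ggplot objects", {
  cfg <- chain3_config(n = 2000, seed = 30, b21 = 0.7, b32 = 0.5)
  tbl <- generate_standardized(cfg)
  fit <- significance_filter(fit_b_matrix(tbl, c("x1", "x2", "x3")))
  expect_s3_class(autoplot(diagram_spec(fit)), "ggplot")
  boot <- bootstrap_lingam(tbl, n_reps = 3, seed = 6)
  expect_s3_class(autoplot(boot), "ggplot")
  curve <- tibble::tibble(sample_size = c(1000L, 2000L),
                          modal_frequency = c(0.5, 0.9))
  expect_s3_class(plot_stability_curve(curve), "ggplot")
})
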