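test_that("config validation enforces the planted-model invariants", {
  nm <- c("a", "b")
  B_up <- matrix(c(0, 0, 0.5, 0), 2, 2, dimnames = list(nm, nm))
  expect_error(checkup_config(nm, B_up, n = 10),
               "lower triangular")
  B_ok <- matrix(c(0, 0, 0.5, 0), 2, 2, byrow = TRUE,
                 dimnames = list(nm, nm))
  expect_error(checkup_config(nm, B_ok, n = 10, noise = "gaussian"),
               "Gaussian")
  expect_error(checkup_config(nm, B_ok, n = 1), "n >= 2")
  # a coefficient of 1.2 puts the parent variance above 1
  B_big <- matrix(c(0, 0, 1.2, 0), 2, 2, byrow = TRUE,
                  dimnames = list(nm, nm))
  expect_error(checkup_config(nm, B_big, n = 10), "disturbance")
})

test_that("all-zero B yields independent columns", {
  nm <- paste0("v", 1:4)
  cfg <- checkup_config(nm, matrix(0, 4, 4, dimnames = list(nm, nm)),
                        n = 50000, seed = 42)
  tbl <- generate_standardized(cfg)
  cm <- cor(as.matrix(tbl[-1]))
  expect_lt(max(abs(cm[upper.tri(cm)])), 4 / sqrt(50000))
})

test_that("sample covariance converges to the closed-form SEM covariance", {
  cfg <- default_checkup_config(n = 1e5, seed = 7)
  tbl <- generate_standardized(cfg)
  S <- planted_covariance(cfg)
  expect_equal(unname(diag(S)), rep(1, 11))
  emp <- cor(as.matrix(tbl[-1]))[rownames(S), colnames(S)]
  expect_lt(max(abs(emp - S)), 3 / sqrt(1e5) + 0.003)
})

test_that("a planted two-variable edge is recovered by OLS", {
  cfg <- pair_config(n = 50000, seed = 3, b21 = 0.687)
  tbl <- generate_standardized(cfg)
  slope <- cov(tbl$x2, tbl$x1) / var(tbl$x1)
  expect_equal(slope, 0.687, tolerance = 0.02)
})

test_that("generation is reproducible and non-Gaussian", {
  cfg <- default_checkup_config(n = 500, seed = 11)
  expect_identical(generate_standardized(cfg), generate_standardized(cfg))
  # disturbance families keep documented distance from Gaussian kurtosis
  set.seed(1)
  ek <- function(x) mean((x - mean(x))^4) / var(x)^2 - 3
  lap <- dlingam:::rnoise(2e5, "laplace")
  uni <- dlingam:::rnoise(2e5, "uniform")
  mix <- dlingam:::rnoise(2e5, "skewed-mixture")
  expect_gt(ek(lap), 2)          # population excess kurtosis 3
  expect_lt(ek(uni), -1)         # population excess kurtosis -1.2
  expect_gt(ek(mix), 2.5)        # analytic value 3.80
  skew <- mean(mix^3) / sd(mix)^3
  expect_gt(skew, 1.3)           # analytic value 1.69
  expect_lt(abs(mean(lap)), 0.02)
  expect_equal(sd(mix), 1, tolerance = 0.02)
})

test_that("rescale_to_units hits the marginal targets and inverts", {
  cfg <- default_checkup_config(n = 20000, seed = 5)
  std <- generate_standardized(cfg)
  raw <- rescale_to_units(std, cfg)
  expect_equal(mean(raw$HbA1c), 5.72, tolerance = 0.03)
  expect_equal(sd(raw$HbA1c), 0.63, tolerance = 0.03)
  expect_equal(mean(raw$height), 157.87, tolerance = 0.3)
  # (0, 1) marginals leave the table unchanged
  nm <- c("u", "v")
  cfg01 <- checkup_config(nm, matrix(0, 2, 2, dimnames = list(nm, nm)),
                          n = 100, seed = 1,
                          marginals = tibble::tibble(index = nm, mean = 0,
                                                     sd = 1))
  t01 <- generate_standardized(cfg01)
  expect_equal(rescale_to_units(t01, cfg01)$u, t01$u)
  # nonpositive sd rejected
  bad <- cfg01
  bad$marginals$sd[1] <- 0
  expect_error(rescale_to_units(t01, bad), "positive")
})

test_that("inject_defects plants the expected defects and records them", {
  cfg <- default_checkup_config(n = 10000, seed = 9)
  tbl <- generate_standardized(cfg)
  expect_equal(as.data.frame(inject_defects(tbl, 0, 0, seed = 1)),
               as.data.frame(tbl), ignore_attr = TRUE)
  bad <- inject_defects(tbl, missing_rate = 0.01, outlier_rate = 0.002,
                        seed = 9)
  log <- attr(bad, "defect_log")
  n_cells <- 10000 * 11
  expect_equal(nrow(log$missing), 0.01 * n_cells,
               tolerance = 5 * sqrt(0.01 * n_cells) / (0.01 * n_cells))
  expect_identical(sum(is.na(as.matrix(bad[-1]))), nrow(log$missing))
  # injected outliers sit beyond the clean columns' extreme quantiles
  for (k in seq_len(min(nrow(log$outliers), 50))) {
    col <- log$outliers$index[k]
    q <- quantile(tbl[[col]], c(0.0005, 0.9995), names = FALSE)
    v <- log$outliers$value[k]
    expect_true(v < q[1] || v > q[2])
  }
  expect_identical(inject_defects(tbl, 0.01, 0.002, seed = 9), bad)
})

test_that("sentinel recoding and CSV round trips preserve the table", {
  cfg <- default_checkup_config(n = 50, seed = 2)
  tbl <- rescale_to_units(generate_standardized(cfg), cfg)
  tbl$BMI[3] <- 999
  rec <- recode_sentinels(tbl, sentinels = 999)
  expect_true(is.na(rec$BMI[3]))
  expect_equal(rec$BMI[-3], tbl$BMI[-3])
  path <- withr::local_tempfile(fileext = ".csv")
  write_checkup_csv(rec, path)
  header <- readLines(path, n = 1)
  expect_identical(header, paste(c("id", checkup_indices()), collapse = ","))
  back <- read_checkup_csv(path)
  expect_true(is.na(back$BMI[3]))
  expect_equal(as.data.frame(back), as.data.frame(rec),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("generator config serializes losslessly to JSON", {
  cfg <- default_checkup_config(n = 123, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkup_config(cfg, path)
  back <- read_checkup_config(path)
  expect_identical(back$order, cfg$order)
  expect_equal(back$b_matrix, cfg$b_matrix)
  expect_identical(back$noise, cfg$noise)
  expect_identical(back$n, cfg$n)
  expect_identical(generate_standardized(back), generate_standardized(cfg))
})

test_that("the shipped default config encodes the reference model", {
  path <- system.file("extdata", "default_config.json", package = "dlingam")
  cfg <- read_checkup_config(path)
  expect_identical(cfg$order, default_causal_order())
  expect_equal(cfg$b_matrix, default_b_matrix())
  expect_identical(cfg$n, 131036L)
})
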