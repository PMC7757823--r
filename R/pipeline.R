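#' Configure an end-to-end analysis run
#'
#' Bundles every knob of the pipeline: the data source (a generator
#' configuration or a CSV path), the index subset, cleaning fraction,
#' regularization, bootstrap size, diagram threshold, seeds and output
#' directory.  The 8-index variant (dropping GOT, fBG and height, whose
#' orderings are the fragile ones) is expressed through `indices`.
#'
#' @param generator A [checkup_config()], or `NULL` when `input_csv` is
#'   given.
#' @param input_csv Path to a checkup CSV, or `NULL` to simulate from
#'   `generator`.
#' @param indices Index subset to analyze; default all columns present.
#' @param frac_per_side Trim fraction per side (default 0.05%).
#' @param lambda,alpha Elasticnet setting (scalars or grids).
#' @param n_reps Bootstrap replicates; 0 skips the bootstrap stage.
#' @param threshold Diagram `|b|` threshold.
#' @param alpha_level Bonferroni family-wise level for edge pruning.
#' @param seed Master seed for every stage.
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @return A `run_config`.
#' @export
run_config <- function(generator = NULL, input_csv = NULL, indices = NULL,
                       frac_per_side = 5e-4, lambda = 0, alpha = 0.5,
                       n_reps = 0, threshold = 0, alpha_level = 0.05,
                       seed = 1L, out_dir = NULL) {
  if (is.null(generator) && is.null(input_csv)) {
    stop("run_config(): supply a generator config or an input CSV",
         call. = FALSE)
  }
  if (!is.null(indices)) {
    stopifnot(length(indices) >= 1, !anyDuplicated(indices))
  }
  stopifnot(frac_per_side >= 0, frac_per_side < 0.5, n_reps >= 0,
            threshold >= 0, alpha_level > 0, alpha_level < 1)
  structure(
    list(generator = generator, input_csv = input_csv, indices = indices,
         frac_per_side = frac_per_side, lambda = lambda, alpha = alpha,
         n_reps = as.integer(n_reps), threshold = threshold,
         alpha_level = alpha_level, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

config_hash <- function(config) {
  # dependency-free provenance hash (djb2 over the serialized config)
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or read) the raw table, clean
#' ([clean_checkup()]), estimate the causal order, fit and
#' significance-filter the structural matrix, optionally bootstrap, and
#' build the diagram.  When `out_dir` is set, every artifact is written
#' there (raw and cleaned CSVs, cleaning report, fitted model JSON, edge
#' CSV + DOT diagram, order-frequency CSV, run manifest); reruns with the
#' same configuration are bit-identical.
#'
#' @param config A [run_config()].
#' @return A list (invisible for its side effects when writing): `config`,
#'   `config_hash`, `cleaning` report, `fit` (`lingam_fit`), `boot`
#'   (`lingam_boot` or `NULL`), `diagram` (`diagram_spec`), `artifacts`
#'   (named paths written).
#' @export
#' @examples
#' cfg <- run_config(generator = default_checkup_config(n = 2000, seed = 1))
#' res <- run_pipeline(cfg)
#' res$fit$order
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  artifacts <- character()
  out <- function(name) {
    path <- file.path(config$out_dir, name)
    artifacts[[name]] <<- path
    path
  }
  # --- ingest ---------------------------------------------------------------
  if (!is.null(config$input_csv)) {
    raw <- read_checkup_csv(config$input_csv)
  } else {
    gen <- config$generator
    raw <- generate_standardized(gen)
    raw <- rescale_to_units(raw, gen)
    if (gen$missing_rate > 0 || gen$outlier_rate > 0) {
      raw <- inject_defects(raw, gen$missing_rate, gen$outlier_rate,
                            seed = gen$seed)
    }
  }
  if (!is.null(config$indices)) {
    keep <- intersect(names(raw), c("id", config$indices))
    missing <- setdiff(config$indices, names(raw))
    if (length(missing) > 0) {
      stop("run_pipeline(): indices not in input: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    raw <- raw[keep]
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_checkup_csv(raw, out("raw.csv"))
  }
  # --- clean ----------------------------------------------------------------
  cleaned <- clean_checkup(raw, frac_per_side = config$frac_per_side)
  report <- cleaning_report(cleaned)
  if (!is.null(config$out_dir)) {
    write_checkup_csv(cleaned, out("cleaned.csv"))
    write_cleaning_report(report, out("cleaning_report.json"))
  }
  # --- estimate -------------------------------------------------------------
  ord <- estimate_order(cleaned)
  fit <- fit_b_matrix(cleaned, ord, lambda = config$lambda,
                      alpha = config$alpha, cv_seed = config$seed)
  fit <- significance_filter(fit, alpha_level = config$alpha_level)
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(
      list(order = fit$order, B = unclass(fit$B),
           significant = unclass(fit$significant),
           lambda = fit$lambda, alpha = fit$alpha, n = fit$n),
      out("model.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(tidy(fit), out("edges.csv"))
  }
  # --- bootstrap ------------------------------------------------------------
  boot <- NULL
  if (config$n_reps > 0) {
    boot <- bootstrap_lingam(cleaned, n_reps = config$n_reps,
                             seed = config$seed, lambda = fit$lambda,
                             alpha = fit$alpha)
    if (!is.null(config$out_dir)) {
      write_order_counts(boot, out("order_counts.csv"))
      readr::write_csv(tidy(boot), out("bootstrap_coefficients.csv"))
    }
  }
  # --- report ---------------------------------------------------------------
  diagram <- diagram_spec(fit, threshold = config$threshold)
  if (!is.null(config$out_dir)) {
    export_diagram(fit, dot_path = out("diagram.dot"),
                   csv_path = out("diagram_edges.csv"),
                   threshold = config$threshold)
    manifest <- list(config_hash = config_hash(config),
                     seed = config$seed,
                     n_records_raw = nrow(raw),
                     n_records_clean = nrow(cleaned),
                     indices = setdiff(names(cleaned), "id"),
                     order = fit$order,
                     lambda = fit$lambda, alpha = fit$alpha,
                     n_reps = config$n_reps,
                     threshold = config$threshold,
                     artifacts = as.list(artifacts))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(list(config = config, config_hash = config_hash(config),
                 cleaning = report, fit = fit, boot = boot,
                 diagram = diagram, artifacts = artifacts))
}

#' Write small planted fixture datasets
#'
#' Generates tiny planted datasets for tests and examples: a 3-variable
#' chain with known coefficients and an 11-index table from the reference
#' model (both n = 2000), written as checkup CSVs with their generator
#' configurations alongside.  Regeneration with the same seed is
#' bit-identical.
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @return Named character vector of written paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  chain_b <- matrix(0, 3, 3,
                    dimnames = list(c("x1", "x2", "x3"),
                                    c("x1", "x2", "x3")))
  chain_b["x2", "x1"] <- 0.8
  chain_b["x3", "x2"] <- 0.8
  chain_cfg <- checkup_config(order = c("x1", "x2", "x3"),
                              b_matrix = chain_b, n = 2000,
                              seed = derive_seed(seed, 11L))
  paths["chain_csv"] <- file.path(dir, "chain3.csv")
  write_checkup_csv(generate_standardized(chain_cfg), paths["chain_csv"])
  paths["chain_config"] <- file.path(dir, "chain3_config.json")
  write_checkup_config(chain_cfg, paths["chain_config"])

  full_cfg <- default_checkup_config(n = 2000,
                                     seed = derive_seed(seed, 12L))
  paths["checkup_csv"] <- file.path(dir, "checkup11.csv")
  write_checkup_csv(
    rescale_to_units(generate_standardized(full_cfg), full_cfg),
    paths["checkup_csv"])
  paths["checkup_config"] <- file.path(dir, "checkup11_config.json")
  write_checkup_config(full_cfg, paths["checkup_config"])
  invisible(paths)
}
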