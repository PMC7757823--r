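#' Health-checkup index names
#'
#' The eleven numeric indices the package models: body-mass index (BMI),
#' the liver enzymes GOT, GPT and gamma-GT, HDL and LDL cholesterol,
#' glycated hemoglobin (HbA1c), triglycerides (TG), fasting blood glucose
#' (fBG), height and systolic blood pressure (sBP).  Gamma-GT is spelled
#' `gGT` everywhere (column names, CSV headers) so that all interfaces stay
#' ASCII-clean.
#'
#' @return Character vector of the 11 index names, in the canonical column
#'   order used by all file interfaces.
#' @export
#' @examples
#' checkup_indices()
checkup_indices <- function() {
  c("BMI", "GOT", "GPT", "HDL", "HbA1c", "LDL", "TG", "fBG",
    "height", "sBP", "gGT")
}

#' Reference marginal summaries of the checkup indices
#'
#' Location/scale (and range) targets that the synthetic generator emulates:
#' per-index mean and standard deviation in raw clinical units, together
#' with the observed min/quartiles/max of the reference population (women in
#' their 70s).  TG and gGT are strongly right-skewed (maximum far above the
#' 75th percentile), which motivates the skewed-mixture disturbance option.
#'
#' @return A tibble with columns `index`, `unit`, `min`, `q25`, `q50`,
#'   `q75`, `max`, `mean`, `sd`.
#' @export
#' @examples
#' checkup_marginals()
checkup_marginals <- function() {
  tibble::tribble(
    ~index,   ~unit,     ~min,  ~q25, ~q50,  ~q75,  ~max,   ~mean,  ~sd,
    "BMI",    "kg/m2",   13.8,  20.5, 22.6,  24.8,  40.9,   22.82,  3.35,
    "GOT",    "IU/L",    11,    19,   22,    27,    177,    24.33,  9.32,
    "GPT",    "IU/L",    5,     13,   17,    23,    186,    20.29,  12.18,
    "HDL",    "mg/dL",   25,    52,   62,    74,    144,    63.74,  16.65,
    "HbA1c",  "%",       4.5,   5.4,  5.6,   5.9,   13.1,   5.72,   0.63,
    "LDL",    "mg/dL",   32,    102,  121,   142,   260,    122.67, 30.51,
    "TG",     "mg/dL",   26,    70,   95,    131,   1009,   110.45, 66.37,
    "fBG",    "mg/dL",   62,    88,   94,    103,   310,    98.53,  19.28,
    "height", "cm",      129.1, 151,  157.3, 164.5, 186.1,  157.87, 9.17,
    "sBP",    "mmHg",    81,    118,  130,   140,   207,    129.64, 17.49,
    "gGT",    "IU/L",    8,     16,   22,    36,    804,    33.97,  40.70
  )
}

#' Reference causal order of the checkup indices
#'
#' The modal causal order estimated for the reference population (women in
#' their 70s): height first, then sBP, LDL, HDL, BMI, TG, GPT, fBG, gGT,
#' HbA1c and GOT last.  This is the topological order of the planted
#' structural model shipped with the package.
#'
#' @return Character vector: a permutation of [checkup_indices()] from
#'   earliest (most exogenous) to latest.
#' @export
#' @examples
#' default_causal_order()
default_causal_order <- function() {
  c("height", "sBP", "LDL", "HDL", "BMI", "TG", "GPT", "fBG",
    "gGT", "HbA1c", "GOT")
}

#' Reference structural coefficient matrix
#'
#' The standardized-scale structural matrix B of the planted model: entry
#' `B[i, j]` is the coefficient of source index `j` in the structural
#' equation of target index `i` (rows are influenced by columns).  Rows and
#' columns follow [default_causal_order()], so B is strictly lower
#' triangular.  Notable entries: fBG drives HbA1c (0.687), GPT drives GOT
#' (0.801), HDL lowers BMI (-0.291) and TG (-0.421), sBP raises BMI
#' (0.151), height lowers BMI (-0.126).
#'
#' @return An 11 x 11 numeric matrix with dimnames in causal order.
#' @export
#' @examples
#' B <- default_b_matrix()
#' B["HbA1c", "fBG"]
default_b_matrix <- function() {
  ord <- default_causal_order()
  B <- matrix(0, 11, 11, dimnames = list(ord, ord))
  B["sBP", "height"] <- -0.030
  B["LDL", c("height", "sBP")] <- c(0.025, 0.045)
  B["HDL", c("height", "sBP", "LDL")] <- c(-0.008, -0.030, -0.019)
  B["BMI", c("height", "sBP", "LDL", "HDL")] <-
    c(-0.126, 0.151, -0.015, -0.291)
  B["TG", c("height", "sBP", "LDL", "HDL", "BMI")] <-
    c(0.020, 0.054, 0.085, -0.421, 0.107)
  B["GPT", c("height", "sBP", "LDL", "HDL", "BMI", "TG")] <-
    c(0.027, 0.006, -0.060, 0.020, 0.175, 0.098)
  B["fBG", c("height", "sBP", "LDL", "HDL", "BMI", "TG", "GPT")] <-
    c(0.028, 0.066, -0.038, -0.031, 0.140, 0.089, 0.109)
  B["gGT", c("height", "sBP", "LDL", "HDL", "BMI", "TG", "GPT", "fBG")] <-
    c(-0.002, 0.008, -0.018, 0.061, 0.016, 0.107, 0.381, 0.046)
  B["HbA1c", c("height", "sBP", "LDL", "HDL", "BMI", "TG", "GPT", "fBG",
               "gGT")] <-
    c(-0.014, -0.028, -0.002, -0.044, 0.033, 0.012, 0.041, 0.687, -0.021)
  B["GOT", c("height", "sBP", "LDL", "HDL", "BMI", "TG", "GPT", "fBG",
             "gGT", "HbA1c")] <-
    c(-0.037, 0.009, -0.026, 0.022, -0.089, -0.036, 0.801, -0.031,
      0.064, -0.043)
  B
}
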