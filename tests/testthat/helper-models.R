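# Small planted models shared across tests.

chain3_config <- function(n = 2000, seed = 1, b21 = 0.8, b32 = 0.8,
                          noise = "laplace") {
  nm <- c("x1", "x2", "x3")
  B <- matrix(0, 3, 3, dimnames = list(nm, nm))
  B["x2", "x1"] <- b21
  B["x3", "x2"] <- b32
  checkup_config(order = nm, b_matrix = B, n = n, noise = noise, seed = seed)
}

pair_config <- function(n = 2000, seed = 1, b21 = 0.687,
                        noise = "laplace") {
  nm <- c("x1", "x2")
  B <- matrix(0, 2, 2, dimnames = list(nm, nm))
  B["x2", "x1"] <- b21
  checkup_config(order = nm, b_matrix = B, n = n, noise = noise, seed = seed)
}

# Pure-R reference implementation of the entropy approximation, kept
# independent of the compiled path it checks.
ref_entropy <- function(x) {
  0.5 * (1 + log(2 * pi)) -
    79.047 * (mean(log(cosh(x))) - 0.37457)^2 -
    7.4129 * (mean(x * exp(-x^2 / 2)))^2
}

# Pure-R pairwise measure built from ref_entropy and explicit residuals.
ref_pairwise <- function(xi, xj) {
  std <- function(v) (v - mean(v)) / sd(v)
  xi <- std(xi); xj <- std(xj)
  ri <- std(xi - cov(xi, xj) / var(xj) * xj)
  rj <- std(xj - cov(xj, xi) / var(xi) * xi)
  (ref_entropy(xj) + ref_entropy(ri)) - (ref_entropy(xi) + ref_entropy(rj))
}

std_laplace <- function(n) (rexp(n) - rexp(n)) / sqrt(2)
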