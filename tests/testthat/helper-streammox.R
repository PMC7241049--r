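# shared fixtures and independent oracles

# default synthetic panel used across tests (computed once per test run)
default_panel <- function() {
  if (is.null(.test_cache$panel)) .test_cache$panel <- gen_sites(14, seed = 1)
  .test_cache$panel
}
.test_cache <- new.env()

# independent oracle for the closed Michaelis-Menten batch: solve the
# implicit form K ln(C0/C) + (C0 - C) = a t by plain bisection
mm_oracle_bisect <- function(C0, a, ks, t) {
  vapply(t, function(tt) {
    if (a * tt <= 0) return(C0)
    g <- function(C) ks * log(C0 / C) + (C0 - C) - a * tt
    lo <- C0 * 1e-16; hi <- C0
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# brute-force headspace equilibrium: bisection on the two-phase mass balance
headspace_oracle <- function(C_w, kh, vw_mL, vg_mL, vd_mL, temp_C, press) {
  vw <- vw_mL / 1000; vg <- vg_mL / 1000
  R <- 0.0820573661; TK <- temp_C + 273.15
  n_tot <- C_w * 1e-6 * vw
  f <- function(p) kh * p * vw + p * vg / (R * TK) - n_tot
  lo <- 0; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  p <- (lo + hi) / 2
  p * vg_mL / vd_mL / press * 1e6
}

# symmetric Procrustes error between two configurations (rotation,
# reflection, scaling and translation removed), as a fraction of total
# variance of the target
procrustes_error <- function(target, config) {
  X <- scale(target, scale = FALSE)
  Y <- scale(config, scale = FALSE)
  X <- X / sqrt(sum(X^2))
  Y <- Y / sqrt(sum(Y^2))
  s <- svd(crossprod(X, Y))
  1 - sum(s$d)^2
}
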