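# internal helpers shared across modules

# evaluate expr with a private RNG stream; restores caller's .Random.seed
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# multiplicative lognormal noise with a given coefficient of variation;
# cv = 0 returns x unchanged (no RNG draw)
lnoise <- function(x, cv, n = length(x)) {
  if (cv <= 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# adjusted Rand index between two label vectors (Hubert & Arabie)
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
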