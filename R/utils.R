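# Seeded-RNG scoping: set a seed for internal draws, restore the caller's
# generator state on exit so package functions do not disturb user RNG.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

# Deterministic sub-seed derivation (stage string + index), kept < 2^31.
derive_seed <- function(seed, stage, i = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1299721 + i * 7919) %% 2147483563) + 1L
}

logdet <- function(m) {
  d <- determinant(as.matrix(m), logarithm = TRUE)
  if (d$sign <= 0) stop("matrix is not positive definite")
  as.numeric(d$modulus)
}

# KL( N(m1, S1) || N(m0, S0) ) for column-mean vectors and covariance matrices.
kl_gauss <- function(m1, S1, m0, S0) {
  p <- length(m1)
  P0 <- solve(S0)
  d <- as.numeric(m1 - m0)
  0.5 * (sum(diag(P0 %*% S1)) + sum(d * (P0 %*% d)) - p + logdet(S0) - logdet(S1))
}
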