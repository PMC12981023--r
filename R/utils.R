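# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All generators route their randomness
# through this so they are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Separable Gaussian blur of a matrix, replicate-padded boundaries.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
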