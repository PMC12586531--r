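# Hierarchical random streams.
#
# Common random numbers across scenario arms require that every stochastic
# event draws from a stream identified by (master seed, iteration, purpose,
# year, condition) and indexed by simulant id -- never from a shared cursor
# whose position depends on what happened earlier in the run. Streams are
# realised by hashing the key to a 32-bit seed and drawing the whole vector
# of uniforms in id order under a locally-set seed.

# Polynomial string hash folded into [1, 2^31 - 2]. 31 * x + c stays well
# below 2^53, so double arithmetic is exact before each modulo.
hash_key <- function(key) {
  chars <- utf8ToInt(key)
  h <- 7
  m <- 2147483647
  for (c in chars) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 2L) + 1L)
}

stream_seed <- function(master_seed, iteration, purpose, year = 0L, tag = "") {
  hash_key(paste(master_seed, iteration, purpose, year, tag, sep = "|"))
}

# Draw n uniforms from a named stream without disturbing the caller's RNG
# state. Identical keys always give identical vectors.
runif_stream <- function(n, master_seed, iteration, purpose, year = 0L, tag = "") {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(master_seed, iteration, purpose, year, tag))
  runif(n)
}

# Standard-normal variant of runif_stream.
rnorm_stream <- function(n, master_seed, iteration, purpose, year = 0L, tag = "") {
  qnorm(pmin(pmax(runif_stream(n, master_seed, iteration, purpose, year, tag),
                  1e-12), 1 - 1e-12))
}

# Inverse-CDF draw from a symmetric triangular distribution on [lo, hi].
qtriangular <- function(p, lo, hi) {
  mid <- (lo + hi) / 2
  ifelse(p < 0.5,
         lo + (hi - lo) * sqrt(p / 2),
         hi - (hi - lo) * sqrt((1 - p) / 2))
}
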