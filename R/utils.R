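## Internal helpers: seeded RNG streams that do not disturb the global
## generator state, seed derivation, and small numeric utilities.

# A self-contained RNG stream. Each draw swaps the stream's state into the
# global generator, draws, and swaps the previous global state back, so
# package functions are deterministic given `seed` and leave the caller's
# RNG untouched.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = genv)
  if (had) assign(".Random.seed", old, envir = genv)
  else rm(".Random.seed", envir = genv)

  draw <- function(expr) {
    had2 <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old2 <- if (had2) get(".Random.seed", envir = genv) else NULL
    assign(".Random.seed", env$state, envir = genv)
    on.exit({
      env$state <- get(".Random.seed", envir = genv)
      if (had2) assign(".Random.seed", old2, envir = genv)
      else rm(".Random.seed", envir = genv)
    })
    expr
  }
  list(
    unif = function(n, min = 0, max = 1) draw(stats::runif(n, min, max)),
    norm = function(n, mean = 0, sd = 1) draw(stats::rnorm(n, mean, sd)),
    int = function(n) draw(sample.int(n, 1L)),
    int_except = function(n, exclude) {
      ok <- setdiff(seq_len(n), exclude)
      ok[draw(sample.int(length(ok), 1L))]
    },
    shuffle = function(x) if (length(x) <= 1L) x else draw(sample(x))
  )
}

# Derive a child seed from a parent seed and an index; stays below 2^31.
derive_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer(((s * 48271 + as.double(k) * 16807) %% 2147483629) + 1)
}

# Batch linear convolution of the columns of S with one kernel, via FFT
# at a 5-smooth padded length, truncated to nrow(S).
fft_conv_batch <- function(S, kernel) {
  n <- nrow(S)
  np <- stats::nextn(n + length(kernel) - 1L, c(2L, 3L, 5L))
  Hf <- stats::fft(c(kernel, numeric(np - length(kernel))))
  Sf <- stats::mvfft(rbind(S, matrix(0, np - n, ncol(S))))
  out <- Re(stats::mvfft(Sf * Hf, inverse = TRUE)) / np
  out[seq_len(n), , drop = FALSE]
}
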