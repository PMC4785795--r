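# Internal numerical helpers shared across modules.

# Derive a deterministic sub-stream seed from a master seed. Kept well below
# .Machine$integer.max so user seeds up to ~1e6 are safe.
sub_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 599479L) * 3581L + as.integer(k) * 127L
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Analytic signal via the frequency-domain Hilbert transform: zero the negative
# frequencies, double the positive ones. Returns a complex vector whose modulus
# is the instantaneous envelope.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Gaussian kernel smoothing with edge replication; sd in samples.
gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0 || length(x) < 2L) return(x)
  r <- ceiling(4 * sd_samples)
  k <- stats::dnorm(seq(-r, r), sd = sd_samples)
  k <- k / sum(k)
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  out <- as.numeric(stats::filter(xp, k, sides = 2))
  out[(r + 1L):(r + length(x))]
}

# Pink (1/f power) Gaussian noise of unit SD, via FFT amplitude shaping.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  idx <- 0:(n - 1)
  f <- pmin(idx, n - idx)       # symmetric frequency index
  amp <- 1 / sqrt(pmax(f, 1))   # 1/sqrt(f) amplitude -> 1/f power
  amp[1] <- 0                   # drop DC
  x <- Re(stats::fft(W * amp, inverse = TRUE) / n)
  x / stats::sd(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
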