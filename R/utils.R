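#' @import methods
#' @importFrom stats fft rnorm runif sd shapiro.test t.test wilcox.test
#'   cor cor.test p.adjust pt complete.cases setNames
#' @importFrom utils read.csv write.csv head
NULL

## FFT-based linear convolution of a signal with a (short) FIR kernel.
## Zero-phase for symmetric odd-length kernels after group-delay removal.
fftConvolve <- function(x, h) {
  n <- length(x)
  m <- length(h)
  nfft <- stats::nextn(n + m - 1L, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - n))) * fft(c(h, numeric(nfft - m))),
              inverse = TRUE)) / nfft
  y[seq_len(n + m - 1L)]
}

## Apply a linear-phase FIR kernel with group-delay compensation so the
## output is time-aligned with the input (zero-phase overall). The kernel
## must have odd length (type-I symmetric FIR). Edges are handled by
## symmetric signal extension to limit transient artifacts.
applyFirZeroPhase <- function(x, h) {
  m <- length(h)
  if (m %% 2L == 0L)
    stop("FIR kernel must have odd length for exact delay compensation")
  half <- (m - 1L) / 2L
  n <- length(x)
  pad <- min(half, n - 1L)
  ## reflect about the end points
  xe <- c(2 * x[1L] - x[pad + 2L - seq_len(pad)],
          x,
          2 * x[n] - x[n - seq_len(pad)])
  y <- fftConvolve(xe, h)
  y[(pad + half) + seq_len(n)]
}

## Windowed-sinc FIR design via signal::fir1 (Hamming window); order from a
## transition-width heuristic, forced even so length is odd.
firOrder <- function(fs, transition_hz, max_order = 8192L) {
  n <- ceiling(3.3 * fs / transition_hz)
  n <- min(n, max_order)
  if (n %% 2L == 1L) n <- n + 1L
  as.integer(max(n, 10L))
}

## Deterministic child seeds derived from one master seed (all < 2^31).
deriveSeeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## Evaluate an expression under a local RNG state (seed), restoring the
## caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}
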