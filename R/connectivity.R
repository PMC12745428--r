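#' Short-time Fourier transform of an epoch set
#'
#' Hann-tapered sliding-window spectra of every trial and channel on an
#' exact 1-Hz frequency grid (windows are zero-padded to one second of
#' samples, since a 0.4 s window natively yields 2.5 Hz spacing). By
#' default only the post-cue action period (`t >= 0`) enters the analysis;
#' the baseline second is excluded.
#'
#' @param ep an [EpochSet-class].
#' @param window_s analysis window length in seconds (default 0.4).
#' @param hop_s hop between window starts (default 0.2, i.e. 50% overlap).
#' @param fmin,fmax frequency grid limits in Hz (defaults 1 and 30).
#' @param post_only if `TRUE` (default) restrict to samples at or after
#'   the cue.
#' @return A [SpectralArray-class] of complex coefficients, trials x
#'   channels x frequencies x windows.
#' @export
stftEpochs <- function(ep, window_s = 0.4, hop_s = 0.2, fmin = 1, fmax = 30,
                       post_only = TRUE) {
  fs <- ep@fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("stftEpochs requires an integer sampling rate for the 1-Hz grid")
  dat <- ep@data
  if (post_only && ep@t0 < 0) {
    skip <- round(-ep@t0 * fs)
    dat <- dat[, , -seq_len(skip), drop = FALSE]
  }
  d <- dim(dat)
  win_n <- round(window_s * fs)
  hop_n <- max(1L, round(hop_s * fs))
  if (win_n < 2) stop("window too short (< 2 samples)")
  if (win_n > d[3L]) stop("window longer than the analyzed epoch segment")
  nfft <- as.integer(round(fs))            # 1-Hz bin spacing
  if (win_n > nfft) nfft <- win_n
  freqs <- seq(fmin, fmax)
  if (max(freqs) >= fs / 2) stop("frequency grid exceeds Nyquist")
  bins <- freqs * nfft / round(fs) + 1L    # DFT bin index of each grid freq
  starts <- seq(1L, d[3L] - win_n + 1L, by = hop_n)
  taper <- hannWindow(win_n)
  coeffs <- array(complex(real = 0), c(d[1L], d[2L], length(freqs),
                                       length(starts)))
  buf <- matrix(0, nfft, d[2L])
  for (tr in seq_len(d[1L])) {
    for (w in seq_along(starts)) {
      seg <- dat[tr, , starts[w] + seq_len(win_n) - 1L, drop = TRUE]
      if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1L)
      buf[] <- 0
      buf[seq_len(win_n), ] <- t(seg * rep(taper, each = d[2L]))
      sp <- stats::mvfft(buf)
      coeffs[tr, , , w] <- t(sp[bins, , drop = FALSE])
    }
  }
  new("SpectralArray", coeffs = coeffs, freqs = as.numeric(freqs), fs = fs,
      window_s = window_s, labels = ep@labels)
}

#' Cross-spectrum between two channels
#'
#' Elementwise `S_xy = C_x * Conj(C_y)` over trials, frequencies and
#' windows.
#'
#' @param s a [SpectralArray-class].
#' @param ch_x,ch_y channel labels.
#' @return Complex array, trials x frequencies x windows.
#' @export
crossSpectrum <- function(s, ch_x, ch_y) {
  ix <- match(ch_x, s@labels)
  iy <- match(ch_y, s@labels)
  if (is.na(ix)) stop("unknown channel: ", ch_x)
  if (is.na(iy)) stop("unknown channel: ", ch_y)
  d <- dim(s@coeffs)
  x <- array(s@coeffs[, ix, , ], c(d[1L], d[3L], d[4L]))
  y <- array(s@coeffs[, iy, , ], c(d[1L], d[3L], d[4L]))
  x * Conj(y)
}

#' Weighted phase lag index of one frequency's cross-spectra
#'
#' `wPLI = |E[Im(S_xy)]| / E[|Im(S_xy)|]`, the expectation running over
#' all supplied observations (trials and time windows pooled). Weighting
#' by the imaginary component makes the index insensitive to zero-lag
#' (volume-conducted) coupling, whose cross-spectral terms are purely
#' real. When every imaginary part is zero the index is defined as 0.
#'
#' @param cross complex (or already-imaginary numeric) observations of the
#'   cross-spectrum at one frequency.
#' @return Scalar in `[0, 1]`.
#' @examples
#' wpli(complex(imaginary = c(0.1, 0.4, -0.2)))  # 0.3 / 0.7
#' @export
wpli <- function(cross) {
  if (!length(cross)) stop("wpli needs at least one observation")
  im <- if (is.complex(cross)) Im(cross) else as.numeric(cross)
  den <- mean(abs(im))
  if (den == 0) return(0)
  abs(mean(im)) / den
}

## Full pairwise wPLI matrix at one frequency slice.
## A: complex observations x channels matrix.
wpliMatrixAtFreq <- function(A) {
  R <- Re(A); I <- Im(A)
  n <- ncol(A)
  nobs <- nrow(A)
  num <- abs((crossprod(I, R) - crossprod(R, I)) / nobs)
  den <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    v <- abs(I[, i] * R[, j, drop = FALSE] - R[, i] * I[, j, drop = FALSE])
    den[i, j] <- den[j, i] <- colMeans(v)
  }
  out <- matrix(0, n, n)
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]
  diag(out) <- 0
  out
}

#' Band-level wPLI connectivity matrix
#'
#' Evaluates the weighted phase lag index at every 1-Hz grid frequency
#' inside the band and averages across those frequencies for every
#' unordered channel pair. Band membership is half-open `[lo, hi)` except
#' that beta also owns its 30 Hz upper edge, so the four bands tile the
#' grid without double counting. The expectation pools trials and time
#' windows by default; `pool_windows = FALSE` instead computes wPLI per
#' time window (across trials) and averages the per-window indices.
#'
#' @param s a [SpectralArray-class].
#' @param band band name from [standardBands()], or a custom name when
#'   `lo`/`hi` are given.
#' @param lo,hi optional explicit band edges (Hz).
#' @param pool_windows pool windows into the expectation (default `TRUE`).
#' @return A [ConnectivityMatrix-class] (symmetric, zero diagonal,
#'   entries in `[0, 1]`).
#' @export
bandWpli <- function(s, band, lo = NULL, hi = NULL, pool_windows = TRUE) {
  if (is.null(lo) || is.null(hi)) {
    bd <- standardBands()[[match.arg(band, names(standardBands()))]]
    lo <- bd[1]; hi <- bd[2]
  }
  sel <- s@freqs >= lo & s@freqs < hi
  if (hi >= max(s@freqs)) sel <- sel | s@freqs == hi
  if (!any(sel)) stop("no grid frequencies inside the band")
  d <- dim(s@coeffs)
  n <- d[2L]
  acc <- matrix(0, n, n)
  for (f in which(sel)) {
    if (pool_windows) {
      ## reshape (trial, channel, window) -> (trial*window) x channel
      A <- matrix(aperm(array(s@coeffs[, , f, ], c(d[1L], n, d[4L])),
                        c(1L, 3L, 2L)), ncol = n)
      acc <- acc + wpliMatrixAtFreq(A)
    } else {
      wacc <- matrix(0, n, n)
      for (w in seq_len(d[4L])) {
        A <- matrix(s@coeffs[, , f, w], nrow = d[1L], ncol = n)
        wacc <- wacc + wpliMatrixAtFreq(A)
      }
      acc <- acc + wacc / d[4L]
    }
  }
  vals <- acc / sum(sel)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 0
  ConnectivityMatrix(pmin(pmax(vals, 0), 1), band = band, labels = s@labels)
}

#' Per-band connectivity matrices from epochs
#'
#' Convenience wrapper: STFT then [bandWpli()] for each requested band.
#'
#' @param ep an [EpochSet-class].
#' @param bands character vector of band names.
#' @param ... forwarded to [stftEpochs()].
#' @return Named list of [ConnectivityMatrix-class] objects.
#' @export
connectivityFromEpochs <- function(ep, bands = names(standardBands()), ...) {
  s <- stftEpochs(ep, ...)
  out <- lapply(bands, function(b) bandWpli(s, b))
  names(out) <- bands
  out
}
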