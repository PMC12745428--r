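#' Standard EEG frequency bands
#'
#' The four analysis bands: delta (2-4 Hz), theta (4-8 Hz), alpha
#' (8-13 Hz), beta (13-30 Hz). Shared endpoints are resolved half-open
#' (`[lo, hi)`) at connectivity time, with beta additionally owning its
#' 30 Hz upper edge, so no 1-Hz grid frequency is counted twice.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
standardBands <- function() {
  list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

## shared filtering core: design a windowed-sinc FIR with signal::fir1 and
## apply it zero-phase (group-delay compensated) row-wise
filterRecording <- function(rec, edges, type, transition_hz) {
  fs <- samplingRate(rec)
  nyq <- fs / 2
  if (any(edges <= 0) || any(edges >= nyq))
    stop(sprintf("filter edges (%s Hz) must lie strictly inside (0, %g) Hz",
                 paste(edges, collapse = ", "), nyq))
  if (edges[1] >= edges[2]) stop("lower edge must be below upper edge")
  ord <- firOrder(fs, transition_hz,
                  max_order = max(10L, 2L * (ncol(rec@data) %/% 3L) - 2L))
  h <- signal::fir1(ord, edges / nyq, type)
  out <- rec@data
  for (i in seq_len(nrow(out))) out[i, ] <- applyFirZeroPhase(out[i, ], h)
  new("EEGRecording", data = out, fs = fs, labels = rec@labels,
      events = rec@events)
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR bandpass, applied with group
#' delay compensated so the output is zero-phase and cue-locked epochs are
#' not shifted. The filter order follows a transition-width heuristic
#' (about `3.3 * fs / transition_hz` taps).
#'
#' @param rec an [EEGRecording-class].
#' @param lo,hi band edges in Hz; `0 < lo < hi < fs/2`.
#' @param transition_hz transition bandwidth (Hz) controlling filter order.
#' @return Filtered [EEGRecording-class].
#' @examples
#' rec <- generateRecording(coupling = defaultCoupling(noise_sd = 0.5),
#'                          n_trials = 2, fs = 250, tasks = "fist", seed = 1)
#' bandpassFilter(rec, 1, 45)
#' @export
bandpassFilter <- function(rec, lo = 0.1, hi = 45, transition_hz = 1) {
  filterRecording(rec, c(lo, hi), "pass", transition_hz)
}

#' Zero-phase FIR notch (band-stop) filter
#'
#' Band-stop analogue of [bandpassFilter()]; the default 49-51 Hz notch
#' removes mains interference.
#'
#' @inheritParams bandpassFilter
#' @return Filtered [EEGRecording-class].
#' @export
notchFilter <- function(rec, lo = 49, hi = 51, transition_hz = 1) {
  filterRecording(rec, c(lo, hi), "stop", transition_hz)
}

#' Resample a recording
#'
#' Integer-factor decimation with FIR anti-alias lowpass filtering before
#' subsampling. Event indices are rescaled and rounded to the nearest
#' sample of the new rate.
#'
#' @param rec an [EEGRecording-class].
#' @param target_fs new sampling rate; must be positive and divide `fs`.
#' @return Resampled [EEGRecording-class].
#' @export
resampleRecording <- function(rec, target_fs = 500) {
  fs <- samplingRate(rec)
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs > fs) stop("upsampling is not supported")
  if (target_fs == fs) return(rec)
  if (abs(fs / target_fs - round(fs / target_fs)) > 1e-9)
    stop("target_fs must divide fs (integer decimation only)")
  q <- as.integer(round(fs / target_fs))
  ## anti-alias lowpass at 80% of the new Nyquist
  cut <- 0.8 * target_fs / 2
  ord <- firOrder(fs, 0.2 * target_fs / 2,
                  max_order = max(10L, 2L * (ncol(rec@data) %/% 3L) - 2L))
  h <- signal::fir1(ord, cut / (fs / 2), "low")
  keep <- seq(1L, ncol(rec@data), by = q)
  out <- matrix(0, nrow(rec@data), length(keep))
  for (i in seq_len(nrow(rec@data)))
    out[i, ] <- applyFirZeroPhase(rec@data[i, ], h)[keep]
  rownames(out) <- rec@labels
  ev <- rec@events
  if (nrow(ev)) {
    ev$sample <- pmax(1L, as.integer(round((ev$sample - 1L) / q) + 1L))
    ev <- ev[ev$sample <= length(keep), , drop = FALSE]
  }
  new("EEGRecording", data = out, fs = target_fs, labels = rec@labels,
      events = ev)
}

#' Re-reference to the linked A1/A2 earlobes
#'
#' Subtracts the sample-wise mean of the A1 and A2 reference channels from
#' every other channel and drops A1/A2 from the output.
#'
#' @param rec an [EEGRecording-class] whose labels include `A1` and `A2`.
#' @return Re-referenced [EEGRecording-class] without the reference rows.
#' @export
rereferenceLinkedEars <- function(rec) {
  miss <- setdiff(c("A1", "A2"), rec@labels)
  if (length(miss))
    stop("missing reference channel(s): ", paste(miss, collapse = ", "))
  ref <- (rec@data["A1", ] + rec@data["A2", ]) / 2
  keep <- setdiff(rec@labels, c("A1", "A2"))
  out <- rec@data[keep, , drop = FALSE] -
    matrix(ref, length(keep), ncol(rec@data), byrow = TRUE)
  new("EEGRecording", data = out, fs = rec@fs, labels = keep,
      events = rec@events)
}

#' Cut cue-locked epochs
#'
#' Extracts one `[-pre_s, +post_s)` window per cue event of the requested
#' task. Epochs that would cross the recording bounds are dropped (never
#' zero-padded) and the dropped count is reported via a message.
#'
#' @param rec an [EEGRecording-class] with events.
#' @param task task label to epoch.
#' @param pre_s,post_s seconds before/after the cue (defaults 1 and 4; the
#'   cue sample itself opens the action period).
#' @return An [EpochSet-class]; empty (0 trials) with a warning when the
#'   recording has no events of that task.
#' @export
epochRecording <- function(rec, task, pre_s = 1, post_s = 4) {
  fs <- samplingRate(rec)
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)
  len <- npre + npost
  ev <- rec@events[rec@events$task == task, , drop = FALSE]
  if (!nrow(ev)) {
    warning("no events of task '", task, "'; returning an empty EpochSet")
    return(EpochSet(array(0, c(0L, nrow(rec@data), len)), fs = fs,
                    t0 = -pre_s, task = task, labels = rec@labels))
  }
  starts <- ev$sample - npre
  ok <- starts >= 1L & (starts + len - 1L) <= ncol(rec@data)
  if (any(!ok))
    message(sum(!ok), " epoch(s) of task '", task,
            "' dropped at the recording bounds")
  starts <- starts[ok]
  dat <- array(0, c(length(starts), nrow(rec@data), len))
  for (i in seq_along(starts))
    dat[i, , ] <- rec@data[, starts[i] + seq_len(len) - 1L]
  EpochSet(dat, fs = fs, t0 = -pre_s, task = task, labels = rec@labels)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean of the pre-cue interval
#' `[-pre, 0)` (the half-open window excludes the cue sample, which
#' belongs to the action period).
#'
#' @param ep an [EpochSet-class] with `t0 < 0`.
#' @return Baseline-corrected [EpochSet-class].
#' @export
baselineCorrect <- function(ep) {
  if (ep@t0 >= 0) stop("epochs carry no pre-cue baseline (t0 >= 0)")
  nbase <- round(-ep@t0 * ep@fs)
  dat <- ep@data
  base <- apply(dat[, , seq_len(nbase), drop = FALSE], c(1, 2), mean)
  dat <- dat - array(rep(base, dim(dat)[3L]), dim(dat))
  new("EpochSet", data = dat, fs = ep@fs, t0 = ep@t0, task = ep@task,
      labels = ep@labels)
}

#' Mirror lateral channels
#'
#' Swaps the data of every homologous left/right electrode pair and leaves
#' midline channels untouched. Used to pool right-affected subjects with
#' the left-affected majority by treating all subjects as left-affected.
#' An involution: applying it twice restores the input.
#'
#' @param ep an [EpochSet-class].
#' @param montage montage supplying the homolog pair table.
#' @return Mirrored [EpochSet-class].
#' @export
mirrorLateral <- function(ep, montage = standardMontage()) {
  labs <- ep@labels
  perm <- seq_along(labs)
  for (i in seq_along(labs)) {
    lab <- labs[i]
    if (lab %in% montage$midline) next
    if (!lab %in% names(montage$homolog_pairs))
      stop("channel without a homolog pair: ", lab)
    mate <- montage$homolog_pairs[[lab]]
    j <- match(mate, labs)
    if (is.na(j)) stop("homolog of ", lab, " (", mate, ") not present")
    perm[i] <- j
  }
  new("EpochSet", data = ep@data[, perm, , drop = FALSE], fs = ep@fs,
      t0 = ep@t0, task = ep@task, labels = ep@labels)
}
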