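#' EEGRecording: continuous multi-channel EEG
#'
#' Container for a continuous multi-channel EEG recording: a channels x
#' samples numeric matrix (microvolts), its sampling rate, ordered channel
#' labels, and cue events marking motor-task onsets.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot labels character, one unique label per channel (row).
#' @slot events data.frame with columns `sample` (1-based sample index of
#'   the cue) and `task` (one of `"fist"`, `"elbow"`, `"wrist"`).
#' @name EEGRecording-class
#' @aliases EEGRecording
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric", labels = "character",
                 events = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (nrow(object@data) != length(object@labels))
      msg <- c(msg, "one label per data row is required")
    if (anyDuplicated(object@labels))
      msg <- c(msg, "channel labels must be unique")
    if (nrow(object@events)) {
      if (!all(c("sample", "task") %in% names(object@events)))
        msg <- c(msg, "events need columns 'sample' and 'task'")
      else if (any(object@events$sample < 1 |
                   object@events$sample > ncol(object@data)))
        msg <- c(msg, "event sample indices must lie within the recording")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param labels channel labels, one per row of `data`.
#' @param events data.frame with columns `sample`, `task` (may be empty).
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, fs, labels,
                         events = data.frame(sample = integer(),
                                             task = character())) {
  rownames(data) <- labels
  new("EEGRecording", data = data, fs = as.numeric(fs),
      labels = as.character(labels), events = events)
}

#' EpochSet: cue-locked trials
#'
#' Trials x channels x time array cut around task cues, with the time of
#' the first sample relative to the cue (`t0`, seconds; -1 for the standard
#' 1 s pre / 4 s post window) and the task label.
#'
#' @slot data numeric array, trials x channels x time.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot t0 numeric(1), time of the first sample relative to the cue (s).
#' @slot task character(1), task label.
#' @slot labels character, channel labels.
#' @name EpochSet-class
#' @aliases EpochSet
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", fs = "numeric", t0 = "numeric",
                 task = "character", labels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-d array (trials x channels x time)")
    else if (dim(object@data)[2L] != length(object@labels))
      msg <- c(msg, "second dimension must match the number of labels")
    if (length(msg)) msg else TRUE
  })

#' Construct an EpochSet
#' @param data trials x channels x time array.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample relative to the cue (s).
#' @param task task label.
#' @param labels channel labels.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(data, fs, t0, task, labels) {
  new("EpochSet", data = data, fs = as.numeric(fs), t0 = as.numeric(t0),
      task = as.character(task), labels = as.character(labels))
}

#' SpectralArray: short-time Fourier coefficients
#'
#' Complex STFT coefficients on a fixed frequency grid: trials x channels x
#' frequencies x time-windows, from Hann-tapered sliding windows
#' zero-padded so the grid has exact 1-Hz spacing.
#'
#' @slot coeffs complex array, trials x channels x freqs x windows.
#' @slot freqs numeric, frequency grid (Hz), strictly increasing.
#' @slot fs numeric(1), sampling rate of the source epochs.
#' @slot window_s numeric(1), analysis window length (s).
#' @slot labels character, channel labels.
#' @name SpectralArray-class
#' @aliases SpectralArray
#' @exportClass SpectralArray
setClass("SpectralArray",
  representation(coeffs = "array", freqs = "numeric", fs = "numeric",
                 window_s = "numeric", labels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@coeffs)) != 4L)
      msg <- c(msg, "coeffs must be 4-d (trials x channels x freqs x windows)")
    else {
      if (dim(object@coeffs)[2L] != length(object@labels))
        msg <- c(msg, "channel dimension must match labels")
      if (dim(object@coeffs)[3L] != length(object@freqs))
        msg <- c(msg, "frequency dimension must match freqs")
    }
    if (is.unsorted(object@freqs, strictly = TRUE))
      msg <- c(msg, "freqs must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' ConnectivityMatrix: band-level wPLI between all node pairs
#'
#' Symmetric zero-diagonal matrix of band-averaged weighted phase lag index
#' values in `[0, 1]` over the 19 montage nodes.
#'
#' @slot band character(1), band name.
#' @slot values numeric matrix, nodes x nodes, symmetric, zero diagonal.
#' @slot labels character, node labels in montage order.
#' @name ConnectivityMatrix-class
#' @aliases ConnectivityMatrix
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(band = "character", values = "matrix", labels = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v) || nrow(v) != length(object@labels))
      msg <- c(msg, "values must be square with one label per node")
    if (any(abs(v - t(v)) > 1e-12))
      msg <- c(msg, "values must be symmetric")
    if (any(abs(diag(v)) > 0))
      msg <- c(msg, "diagonal must be zero")
    if (any(v < -1e-12 | v > 1 + 1e-12))
      msg <- c(msg, "wPLI values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a ConnectivityMatrix
#' @param values symmetric zero-diagonal numeric matrix with entries in
#'   `[0, 1]`.
#' @param band band name.
#' @param labels node labels (defaults to the matrix dimnames).
#' @return A [ConnectivityMatrix-class] object.
#' @export
ConnectivityMatrix <- function(values, band, labels = rownames(values)) {
  dimnames(values) <- list(labels, labels)
  new("ConnectivityMatrix", band = as.character(band), values = values,
      labels = as.character(labels))
}

#' BinaryGraph: thresholded undirected network
#'
#' Undirected, unweighted adjacency over the montage nodes obtained by
#' keeping the strongest fraction (`sparsity`) of connectivity weights.
#'
#' @slot adjacency 0/1 numeric matrix, symmetric, zero diagonal.
#' @slot sparsity numeric(1), fraction of possible edges retained.
#' @slot labels character, node labels.
#' @name BinaryGraph-class
#' @aliases BinaryGraph
#' @exportClass BinaryGraph
setClass("BinaryGraph",
  representation(adjacency = "matrix", sparsity = "numeric",
                 labels = "character"),
  validity = function(object) {
    a <- object@adjacency
    msg <- character()
    if (nrow(a) != ncol(a) || nrow(a) != length(object@labels))
      msg <- c(msg, "adjacency must be square with one label per node")
    if (!all(a %in% c(0, 1)))
      msg <- c(msg, "adjacency must be binary")
    if (any(a != t(a)))
      msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(a) != 0))
      msg <- c(msg, "self-loops are not allowed")
    if (length(msg)) msg else TRUE
  })

#' Construct a BinaryGraph
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param sparsity fraction of possible edges retained.
#' @param labels node labels (defaults to the matrix dimnames).
#' @return A [BinaryGraph-class] object.
#' @export
BinaryGraph <- function(adjacency, sparsity, labels = rownames(adjacency)) {
  dimnames(adjacency) <- list(labels, labels)
  new("BinaryGraph", adjacency = adjacency, sparsity = as.numeric(sparsity),
      labels = as.character(labels))
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet[%s]: %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              object@task, d[1L], d[2L], d[3L], object@fs, object@t0))
})

setMethod("show", "SpectralArray", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf("SpectralArray: %d trials x %d channels x %d freqs (%g-%g Hz) x %d windows\n",
              d[1L], d[2L], d[3L], min(object@freqs), max(object@freqs), d[4L]))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix[%s]: %d x %d, mean off-diagonal wPLI = %.3f\n",
              object@band, nrow(object@values), ncol(object@values),
              mean(object@values[upper.tri(object@values)])))
})

setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph: %d nodes, %d edges (sparsity %.2f)\n",
              nrow(object@adjacency), sum(object@adjacency) / 2,
              object@sparsity))
})
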