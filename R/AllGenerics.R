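#' Accessors for wpliNet containers
#'
#' Small accessor generics shared by the package's S4 containers:
#' `channelLabels()` returns the ordered channel/node labels,
#' `samplingRate()` the sampling rate in Hz, `eventTable()` the cue event
#' table of a recording, `nTrials()` the trial count of an epoch set, and
#' `adjacency()` / `graphSparsity()` / `bandName()` / `connValues()` the
#' corresponding slots of graphs and connectivity matrices.
#'
#' @param x a wpliNet S4 object.
#' @return The slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("graphSparsity", function(x) standardGeneric("graphSparsity"))
#' @rdname accessors
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))
#' @rdname accessors
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "SpectralArray", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "ConnectivityMatrix", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "BinaryGraph", function(x) x@labels)

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname accessors
setMethod("eventTable", "EEGRecording", function(x) x@events)

#' @rdname accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1L])

#' @rdname accessors
setMethod("adjacency", "BinaryGraph", function(x) x@adjacency)
#' @rdname accessors
setMethod("graphSparsity", "BinaryGraph", function(x) x@sparsity)
#' @rdname accessors
setMethod("bandName", "ConnectivityMatrix", function(x) x@band)
#' @rdname accessors
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)
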