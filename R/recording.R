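#' Construct a multi-channel recording
#'
#' @param data numeric matrix (channels x samples) or an object coercible to
#'   one; a plain vector is treated as a single channel.
#' @param fs sampling rate in Hz.
#' @param channelLabels optional character vector of channel names.
#'
#' @return a [MultiChannelRecording-class] object.
#' @examples
#' rec <- multiChannelRecording(matrix(rnorm(200), nrow = 2), fs = 100)
#' nChannels(rec)
#' @export
multiChannelRecording <- function(data, fs, channelLabels = character()) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (length(channelLabels) == 0L && !is.null(rownames(data)))
    channelLabels <- rownames(data)
  new("MultiChannelRecording", data = data, fs = as.numeric(fs),
    channelLabels = as.character(channelLabels))
}

#' @rdname accessors
#' @export
setMethod("samplingRate", "MultiChannelRecording", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("nChannels", "MultiChannelRecording", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("nSamples", "MultiChannelRecording", function(x) ncol(x@data))

#' @rdname accessors
#' @export
setMethod("channelLabels", "MultiChannelRecording",
  function(x) x@channelLabels)

#' @describeIn multiChannelRecording extract the raw channels x samples matrix.
#' @param x a `MultiChannelRecording`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "MultiChannelRecording", function(x, ...) x@data)

setMethod("show", "MultiChannelRecording", function(object) {
  cat(sprintf("MultiChannelRecording: %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs))
  if (length(object@channelLabels))
    cat("  channels:", paste(utils::head(object@channelLabels, 8L),
      collapse = ", "),
      if (length(object@channelLabels) > 8L) "..." else "", "\n")
})
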