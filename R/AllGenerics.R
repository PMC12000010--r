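#' Accessor generics
#'
#' Small accessor generics shared by the package's classes. Use these rather
#' than reaching into slots with `@`.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname accessors
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' @rdname accessors
#' @export
setGeneric("bandComponents", function(x) standardGeneric("bandComponents"))

#' @rdname accessors
#' @export
setGeneric("commonComponent", function(x) standardGeneric("commonComponent"))

#' @rdname accessors
#' @export
setGeneric("channelComponents", function(x) standardGeneric("channelComponents"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
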