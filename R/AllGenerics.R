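#' @export
setGeneric("hostContains", function(index, query) standardGeneric("hostContains"))

#' @export
setGeneric("addSequences", function(index, seqs) standardGeneric("addSequences"))

#' @export
setGeneric("saveIndex", function(index, path) standardGeneric("saveIndex"))

#' @export
setGeneric("nKmersSet", function(x) standardGeneric("nKmersSet"))

#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @export
setGeneric("indexBackend", function(x) standardGeneric("indexBackend"))

#' @export
setGeneric("bitmapBytes", function(x) standardGeneric("bitmapBytes"))

#' @export
setGeneric("probeSequence", function(x) standardGeneric("probeSequence"))

#' @export
setGeneric("probeRevcomp", function(x) standardGeneric("probeRevcomp"))

#' @export
setGeneric("armSequences", function(x) standardGeneric("armSequences"))

#' @export
setGeneric("armRevcomps", function(x) standardGeneric("armRevcomps"))

#' @export
setGeneric("probeSites", function(x) standardGeneric("probeSites"))

#' @export
setGeneric("probeJunctions", function(x) standardGeneric("probeJunctions"))
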