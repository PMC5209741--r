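#' @rdname ItsCloneSet-class
#' @param x An object.
#' @export
setGeneric("cloneIDs", function(x) standardGeneric("cloneIDs"))

#' @rdname ItsCloneSet-class
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname ItsCloneSet-class
#' @export
setGeneric("cloneSeqs", function(x) standardGeneric("cloneSeqs"))

#' @rdname ItsCloneSet-class
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

#' @rdname ItsCloneSet-class
#' @param value Replacement value.
#' @export
setGeneric("partitions<-", function(x, value) standardGeneric("partitions<-"))

#' @rdname ItsCloneSet-class
#' @param region One of "ITS1", "5.8S", "ITS2".
#' @export
setGeneric("regionSeqs", function(x, region) standardGeneric("regionSeqs"))

#' @rdname SimulatedCloneSet-class
#' @param x An object.
#' @export
setGeneric("simClones", function(x) standardGeneric("simClones"))

#' @rdname SimulatedCloneSet-class
#' @export
setGeneric("simAlignment", function(x) standardGeneric("simAlignment"))

#' @rdname SimulatedCloneSet-class
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname SimulatedCloneSet-class
#' @export
setGeneric("referenceSet", function(x) standardGeneric("referenceSet"))

#' @rdname SimulatedCloneSet-class
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))

#' @rdname SimulatedCloneSet-class
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
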