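#' @rdname MsaAlignment-accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname MsaAlignment-accessors
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname MsaAlignment-accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname MsaAlignment-accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @rdname getColumn
#' @export
setGeneric("getColumn", function(x, j) standardGeneric("getColumn"))

#' @rdname ShuffleNull-accessors
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))

#' @rdname ShuffleNull-accessors
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))

#' @rdname ShuffleNull-accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname SortResult-accessors
#' @export
setGeneric("rowOrder", function(x) standardGeneric("rowOrder"))

#' @rdname SortResult-accessors
#' @export
setGeneric("colOrder", function(x) standardGeneric("colOrder"))

#' @rdname SortResult-accessors
#' @export
setGeneric("sortedMatrix", function(x) standardGeneric("sortedMatrix"))
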