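#' @rdname tandemDims
#' @export
setGeneric("daughterSize", function(x) standardGeneric("daughterSize"))

#' @rdname tandemDims
#' @export
setGeneric("complementSize", function(x) standardGeneric("complementSize"))

#' @rdname tandemDims
#' @export
setGeneric("parentSize", function(x) standardGeneric("parentSize"))

#' @rdname tandemValues
#' @export
setGeneric("tandemValues", function(x) standardGeneric("tandemValues"))

#' @rdname tandemValues
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname marginals
#' @export
setGeneric("parentMarginal", function(x) standardGeneric("parentMarginal"))

#' @rdname marginals
#' @export
setGeneric("daughterMarginal", function(x) standardGeneric("daughterMarginal"))

#' @rdname marginals
#' @export
setGeneric("complementMarginal", function(x) standardGeneric("complementMarginal"))

#' @rdname compaction
#' @export
setGeneric("toCompact", function(x, ...) standardGeneric("toCompact"))

#' @rdname compaction
#' @export
setGeneric("toFull", function(x, ...) standardGeneric("toFull"))
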