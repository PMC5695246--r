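#' @rdname isDescendant
#' @export
setGeneric("isDescendant",
    function(tree, taxid, ancestor) standardGeneric("isDescendant"))

#' @rdname assignClade
#' @export
setGeneric("assignClade",
    function(tree, config, taxid) standardGeneric("assignClade"))

#' @rdname CladeConfig-class
#' @param x a \code{CladeConfig}.
#' @export
setGeneric("cladeLabels", function(x) standardGeneric("cladeLabels"))

#' @rdname CladeConfig-class
#' @export
setGeneric("cladeTaxids", function(x) standardGeneric("cladeTaxids"))

#' @rdname ScreenReport-class
#' @param x a \code{ScreenReport}.
#' @export
setGeneric("reportRows", function(x) standardGeneric("reportRows"))

#' @rdname ScreenReport-class
#' @export
setGeneric("reportTotals", function(x) standardGeneric("reportTotals"))

#' @rdname ScreenReport-class
#' @export
setGeneric("reportMetadata", function(x) standardGeneric("reportMetadata"))

#' @rdname Segmentation-class
#' @param x a \code{Segmentation}.
#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))

#' @rdname Segmentation-class
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname GCDistribution-class
#' @param x a \code{GCDistribution}.
#' @export
setGeneric("gcModes", function(x) standardGeneric("gcModes"))

#' @rdname GCDistribution-class
#' @export
setGeneric("gcValues", function(x) standardGeneric("gcValues"))
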