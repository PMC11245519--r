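#' @rdname OneSiteFit-class
#' @param object,x An object.
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))

#' @rdname OneSiteFit-class
#' @export
setGeneric("deltaH", function(object) standardGeneric("deltaH"))

#' @rdname OneSiteFit-class
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname OneSiteFit-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname TmCall-class
#' @export
setGeneric("tmValue", function(object) standardGeneric("tmValue"))

#' @rdname AlignedBlock-class
#' @export
setGeneric("columnCount", function(object) standardGeneric("columnCount"))

#' @rdname AlignedBlock-class
#' @export
setGeneric("alignmentIds", function(object) standardGeneric("alignmentIds"))

#' @rdname TrimResult-class
#' @export
setGeneric("keptColumns", function(object) standardGeneric("keptColumns"))

#' @rdname MotifDefinition-class
#' @export
setGeneric("motifPositions", function(object) standardGeneric("motifPositions"))

#' @rdname MotifDefinition-class
#' @export
setGeneric("motifSpacings", function(object) standardGeneric("motifSpacings"))

#' @rdname MotifMatch-class
#' @export
setGeneric("variant", function(object) standardGeneric("variant"))

#' Map tracked reference positions to alignment columns
#'
#' @param alignment An [AnchorAlignment] (pairwise) or [AlignedBlock]
#'   (multiple alignment; give `referenceId`).
#' @param anchor A [ReferenceAnchor], or an integer vector of reference
#'   positions (full-length numbering) when `offset` is supplied.
#' @param ... Further arguments passed to methods.
#' @return A [ColumnMap].
#' @export
setGeneric("mapPositions",
           function(alignment, anchor, ...) standardGeneric("mapPositions"))
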