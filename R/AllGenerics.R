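#' @rdname GeneModel
#' @param object,x a package object.
#' @export
setGeneric("geneID", function(object) standardGeneric("geneID"))

#' @rdname GeneModel
#' @export
setGeneric("transcripts", function(object) standardGeneric("transcripts"))

#' @rdname DeletionDesign-class
#' @export
setGeneric("deletionSize", function(object) standardGeneric("deletionSize"))

#' @rdname DeletionDesign-class
#' @export
setGeneric("deletionInterval", function(object) standardGeneric("deletionInterval"))

#' @rdname DeletionDesign-class
#' @export
setGeneric("guidePair", function(object) standardGeneric("guidePair"))

#' @rdname DeletionDesign-class
#' @export
setGeneric("alternatePairs", function(object) standardGeneric("alternatePairs"))

#' @rdname AmpliconPrediction-class
#' @export
setGeneric("productSizes", function(object) standardGeneric("productSizes"))

#' @describeIn GeneModel gene identifier.
#' @export
setMethod("geneID", "GeneModel", function(object) object@geneID)

#' @describeIn GeneModel the CDS chains, a \code{GRangesList} with one
#'   element per transcript.
#' @export
setMethod("transcripts", "GeneModel", function(object) object@transcripts)

#' @describeIn GeneModel gene identifier of a design.
#' @export
setMethod("geneID", "DeletionDesign", function(object) object@geneID)

#' @describeIn DeletionDesign-class deletion size in bp.
#' @export
setMethod("deletionSize", "DeletionDesign", function(object) object@deletionSize)

#' @describeIn DeletionDesign-class excised interval as a \code{GRanges}
#'   (1-based bases removed by the blunt-join model).
#' @export
setMethod("deletionInterval", "DeletionDesign", function(object) {
    GRanges(object@chrom, IRanges(object@cut1 + 1L, object@cut2))
})

#' @describeIn DeletionDesign-class the two chosen guides as a
#'   two-row \code{GRanges} (START then STOP).
#' @export
setMethod("guidePair", "DeletionDesign", function(object) {
    c(object@guideStart, object@guideStop)
})

#' @describeIn DeletionDesign-class runner-up pairs as a data.frame.
#' @export
setMethod("alternatePairs", "DeletionDesign", function(object) object@alternates)

#' @describeIn AmpliconPrediction-class named vector of wild-type and
#'   deletion product sizes (NA when no product).
#' @export
setMethod("productSizes", "AmpliconPrediction", function(object) {
    c(wt = object@wtSize, del = object@delSize)
})
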