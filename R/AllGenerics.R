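#' @rdname Methylome-class
#' @param x a `Methylome` or `GeneModelSet`
#' @export
setGeneric("methSites", function(x) standardGeneric("methSites"))

#' @rdname Methylome-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname Methylome-class
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname Methylome-class
#' @export
setGeneric("nonconversionRate", function(x) standardGeneric("nonconversionRate"))

#' @rdname Methylome-class
#' @param value replacement value
#' @export
setGeneric("nonconversionRate<-",
           function(x, value) standardGeneric("nonconversionRate<-"))

#' @rdname Methylome-class
#' @export
setGeneric("methLevels", function(x) standardGeneric("methLevels"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("utr5Ranges", function(x) standardGeneric("utr5Ranges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("utr3Ranges", function(x) standardGeneric("utr3Ranges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("tes", function(x) standardGeneric("tes"))
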