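#' @include AllClasses.R
NULL

#' Accessor generics for PeakTable and RatingResult objects
#'
#' Small accessor generics following Bioconductor conventions: slot access in
#' user code always goes through these, never through `@`.
#'
#' @param x A [PeakTable] or [RatingResult] object.
#' @param value Replacement value.
#' @name peakRating-generics
NULL

#' @rdname peakRating-generics
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname peakRating-generics
#' @export
setGeneric("mz", function(x) standardGeneric("mz"))

#' @rdname peakRating-generics
#' @export
setGeneric("rt", function(x) standardGeneric("rt"))

#' @rdname peakRating-generics
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @rdname peakRating-generics
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname peakRating-generics
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname peakRating-generics
#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))

#' @rdname peakRating-generics
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname peakRating-generics
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname peakRating-generics
#' @export
setGeneric("clusterIds<-", function(x, value) standardGeneric("clusterIds<-"))

#' @rdname peakRating-generics
#' @export
setGeneric("attributions", function(x) standardGeneric("attributions"))

#' @rdname peakRating-generics
#' @export
setGeneric("attributions<-", function(x, value) standardGeneric("attributions<-"))

#' @rdname peakRating-generics
#' @export
setGeneric("adductLabels", function(x) standardGeneric("adductLabels"))

#' @rdname peakRating-generics
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname peakRating-generics
#' @export
setGeneric("trfGroups", function(x) standardGeneric("trfGroups"))

#' @rdname peakRating-generics
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname peakRating-generics
#' @export
setGeneric("finalIds", function(x) standardGeneric("finalIds"))

#' @rdname peakRating-generics
#' @export
setGeneric("fragmentCalls", function(x) standardGeneric("fragmentCalls"))

#' @rdname peakRating-generics
#' @export
setGeneric("adductAssignments", function(x) standardGeneric("adductAssignments"))
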