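#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname peakRating-generics
#' @export
setMethod("featureIds", "PeakTable", function(x) rowData(x)$feature_id)

#' @rdname peakRating-generics
#' @export
setMethod("mz", "PeakTable", function(x) {
    v <- rowData(x)$mz
    names(v) <- featureIds(x)
    v
})

#' @rdname peakRating-generics
#' @export
setMethod("rt", "PeakTable", function(x) {
    v <- rowData(x)$rt
    names(v) <- featureIds(x)
    v
})

#' @rdname peakRating-generics
#' @export
setMethod("heights", "PeakTable", function(x) assay(x, "height"))

#' @rdname peakRating-generics
#' @export
setMethod("spectra", "PeakTable", function(x) {
    s <- as.list(rowData(x)$ms2)
    names(s) <- featureIds(x)
    s
})

#' @rdname peakRating-generics
#' @export
setMethod("sampleInfo", "PeakTable", function(x)
    as.data.frame(colData(x), row.names = NULL))

#' @rdname peakRating-generics
#' @export
setMethod("polarity", "PeakTable", function(x) metadata(x)$polarity)

#' @rdname peakRating-generics
#' @export
setMethod("provenance", "PeakTable", function(x)
    as.character(metadata(x)$provenance))

#' @rdname peakRating-generics
#' @export
setMethod("clusterIds", "PeakTable", function(x) {
    v <- rowData(x)$cluster_id
    names(v) <- featureIds(x)
    v
})

#' @rdname peakRating-generics
#' @export
setReplaceMethod("clusterIds", "PeakTable", function(x, value) {
    stopifnot(length(value) == nrow(x))
    rowData(x)$cluster_id <- as.character(value)
    validObject(x)
    x
})

#' @rdname peakRating-generics
#' @export
setMethod("attributions", "PeakTable", function(x) {
    v <- rowData(x)$attribution
    names(v) <- featureIds(x)
    v
})

#' @rdname peakRating-generics
#' @export
setReplaceMethod("attributions", "PeakTable", function(x, value) {
    cur <- rowData(x)$attribution
    if (!is.null(names(value))) {
        idx <- match(names(value), featureIds(x))
        if (anyNA(idx))
            stop("unknown feature_id: ",
                 paste(names(value)[is.na(idx)], collapse = ", "))
        new_full <- cur
        new_full[idx] <- unname(value)
    } else {
        stopifnot(length(value) == nrow(x))
        new_full <- as.character(value)
    }
    # attributions only move away from "unrated"
    frozen <- cur != "unrated" & new_full != cur
    if (any(frozen))
        stop("attribution already set for feature(s): ",
             paste(head(featureIds(x)[frozen], 5L), collapse = ", "))
    rowData(x)$attribution <- new_full
    validObject(x)
    x
})

#' @rdname peakRating-generics
#' @export
setMethod("adductLabels", "PeakTable", function(x) {
    v <- rowData(x)$adduct_label
    names(v) <- featureIds(x)
    v
})

#' @rdname peakRating-generics
#' @export
setMethod("groupIds", "PeakTable", function(x) {
    v <- rowData(x)$group_id
    names(v) <- featureIds(x)
    v
})

#' Biological / blank / QC sample ids of a PeakTable
#'
#' @param x A [PeakTable].
#' @return Character vector of sample ids with the requested role.
#' @export
biologicalSamples <- function(x) {
    cd <- colData(x)
    cd$sample_id[cd$role == "biological"]
}

#' @rdname biologicalSamples
#' @export
blankSamples <- function(x) {
    cd <- colData(x)
    cd$sample_id[cd$role == "blank"]
}

#' @rdname biologicalSamples
#' @export
qcSamples <- function(x) {
    cd <- colData(x)
    cd$sample_id[cd$role == "qc"]
}

#' Feature clusters of a PeakTable
#'
#' Returns the partition of features induced by their `cluster_id`, as a named
#' list of feature-id vectors. Features with no cluster id (`NA`) are omitted.
#'
#' @param x A [PeakTable].
#' @param includeInterference keep features already marked as interference?
#'   Default `FALSE` (they are out of the rating game).
#' @return Named list: cluster id -> character vector of feature ids.
#' @export
featureClusters <- function(x, includeInterference = FALSE) {
    cid <- clusterIds(x)
    keep <- !is.na(cid)
    if (!includeInterference)
        keep <- keep & attributions(x) != "interference"
    split(featureIds(x)[keep], cid[keep])
}

.appendProvenance <- function(x, line) {
    metadata(x)$provenance <- c(metadata(x)$provenance, line)
    x
}

setMethod("show", "PeakTable", function(object) {
    cd <- colData(object)
    at <- table(factor(rowData(object)$attribution, levels = .ATTRIBUTION_LEVELS))
    cat(sprintf("PeakTable (%s mode): %d features x %d samples\n",
                polarity(object), nrow(object), ncol(object)))
    cat(sprintf("  samples: %d biological, %d blank, %d QC\n",
                sum(cd$role == "biological"), sum(cd$role == "blank"),
                sum(cd$role == "qc")))
    cat(sprintf("  clusters: %d assigned\n",
                length(unique(stats::na.omit(rowData(object)$cluster_id)))))
    cat("  attributions:",
        paste(sprintf("%s=%d", names(at), as.integer(at)), collapse = " "), "\n")
    if (length(provenance(object)))
        cat("  provenance:", length(provenance(object)), "step(s), last:",
            utils::tail(provenance(object), 1L), "\n")
    invisible(NULL)
})

#' @rdname peakRating-generics
#' @export
setMethod("attributions", "RatingResult", function(x) x@attributions)

#' @rdname peakRating-generics
#' @export
setMethod("trfGroups", "RatingResult", function(x) x@groups)

#' @rdname peakRating-generics
#' @export
setMethod("representatives", "RatingResult", function(x) x@representatives)

#' @rdname peakRating-generics
#' @export
setMethod("finalIds", "RatingResult", function(x) x@final_ids)

#' @rdname peakRating-generics
#' @export
setMethod("fragmentCalls", "RatingResult", function(x) x@fragment_calls)

#' @rdname peakRating-generics
#' @export
setMethod("adductAssignments", "RatingResult", function(x) x@assignments)

setMethod("show", "RatingResult", function(object) {
    at <- table(factor(object@attributions,
                       levels = c("TRF", "SRF", "fragment", "interference")))
    cat("RatingResult:", length(object@attributions), "features\n")
    cat(" ", paste(sprintf("%s=%d", names(at), as.integer(at)), collapse = " "), "\n")
    cat(sprintf("  %d TRF correlation group(s), final table %d feature(s)\n",
                length(object@groups), length(object@final_ids)))
    invisible(NULL)
})
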