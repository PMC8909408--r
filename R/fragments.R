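#' @include AllClasses.R accessors.R
NULL

#' Screen in-source fragments within one feature cluster
#'
#' A feature is called an in-source fragment when its MS1 m/z reappears, to
#' within `tolerance` Da, as a peak in the MS2 spectrum of a heavier member
#' of the same cluster. Features already flagged as TRFs are exempt from
#' being screened (they are established adduct forms, never fragment
#' candidates), though their spectra still serve as owners. All qualifying
#' (fragment, owner) pairs are reported; the minimal-error pair is marked
#' primary. Calls are computed in a single pass against the original cluster
#' state: removal of one fragment never creates or destroys another call.
#'
#' @param table A [PeakTable].
#' @param members character vector of feature ids forming one cluster.
#' @param trfIds feature ids flagged as TRFs (exempt candidates).
#' @param tolerance matching tolerance in Da; default 0.05.
#' @param ms2MinRelIntensity optional floor on the owner MS2 peak, as a
#'   fraction of the owner's base peak; default 0 (any recorded peak
#'   counts).
#' @return `data.frame` with columns `fragment_id`, `owner_id`,
#'   `matched_ms2_mz`, `error_da`, `primary`.
#' @examples
#' pt <- PeakTable(
#'   features = data.frame(feature_id = c("F1", "F2"),
#'                         mz = c(121.0295, 179.0355), rt = c(2.0, 2.0)),
#'   samples = data.frame(sample_id = "S1"),
#'   spectra = list(NULL, cbind(c(93.0346, 121.0295), c(120, 300))))
#' screenFragments(pt, c("F1", "F2"), trfIds = character())
#' @export
screenFragments <- function(table, members, trfIds = character(),
                            tolerance = 0.05, ms2MinRelIntensity = 0) {
    stopifnot(tolerance > 0)
    empty <- data.frame(fragment_id = character(), owner_id = character(),
                        matched_ms2_mz = numeric(), error_da = numeric(),
                        primary = logical())
    if (length(members) < 2L) return(empty)
    miss <- setdiff(members, featureIds(table))
    if (length(miss))
        stop("unknown feature id(s): ", paste(miss, collapse = ", "))
    mzs <- mz(table)[members]
    sp <- spectra(table)[members]
    calls <- empty
    for (fi in seq_along(members)) {
        f <- members[fi]
        if (f %in% trfIds) next
        for (gi in seq_along(members)) {
            g <- members[gi]
            if (g == f || mzs[gi] <= mzs[fi]) next
            s <- sp[[gi]]
            if (nrow(s) == 0L) next
            if (ms2MinRelIntensity > 0) {
                s <- s[s[, 2L] >= ms2MinRelIntensity * max(s[, 2L]), ,
                       drop = FALSE]
                if (nrow(s) == 0L) next
            }
            err <- abs(mzs[fi] - s[, 1L])
            hit <- which(err <= tolerance)
            if (length(hit)) {
                best <- hit[which.min(err[hit])]
                calls <- rbind(calls, data.frame(
                    fragment_id = f, owner_id = g,
                    matched_ms2_mz = s[best, 1L], error_da = err[best],
                    primary = FALSE))
            }
        }
    }
    if (!nrow(calls)) return(empty)
    calls <- calls[order(calls$fragment_id, calls$error_da,
                         mz(table)[calls$owner_id], calls$owner_id), ]
    rownames(calls) <- NULL
    calls$primary <- !duplicated(calls$fragment_id)
    calls
}

#' Classify second-rated features (SRFs) within one cluster
#'
#' After adduct flagging and fragment removal, the cluster members that are
#' neither TRFs nor fragments are the second-rated features: parental
#' features present only as isolated quasi-molecular ions.
#'
#' @param members character vector of feature ids forming one cluster.
#' @param trfIds TRF feature ids.
#' @param fragmentIds fragment feature ids.
#' @return Character vector of SRF feature ids.
#' @export
classifySrf <- function(members, trfIds = character(),
                        fragmentIds = character()) {
    overlap <- intersect(trfIds, fragmentIds)
    if (length(overlap))
        stop("internal consistency error: feature(s) both TRF and fragment: ",
             paste(overlap, collapse = ", "))
    setdiff(members, c(trfIds, fragmentIds))
}
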