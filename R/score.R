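#' @include AllClasses.R accessors.R
NULL

# plain Rand index between two partitions given as membership vectors over
# the same element universe (pair-counting form)
.randIndex <- function(a, b) {
    stopifnot(length(a) == length(b))
    n <- length(a)
    if (n < 2L) return(1)
    tab <- table(a, b)
    sum_comb <- function(x) sum(choose(x, 2L))
    s_ab <- sum_comb(as.vector(tab))
    s_a <- sum_comb(rowSums(tab))
    s_b <- sum_comb(colSums(tab))
    total <- choose(n, 2L)
    (total + 2 * s_ab - s_a - s_b) / total
}

.prf <- function(predicted, expected) {
    tp <- length(intersect(predicted, expected))
    precision <- if (length(predicted)) tp / length(predicted) else 1
    recall <- if (length(expected)) tp / length(expected) else 1
    list(precision = precision, recall = recall,
         n_predicted = length(predicted), n_expected = length(expected))
}

#' Score a rating result against planted ground truth
#'
#' Compares a [RatingResult] with the ground truth of a synthetic table:
#' precision and recall of the TRF (adduct-flag) set, of the fragment calls
#' and of the SRF set, each against the attribution the planted construction
#' implies, plus the Rand index between the predicted feature clustering and
#' the planted per-compound partition. The empty-set convention is precision
#' (or recall) 1 when nothing is predicted (or planted).
#'
#' @param result A [RatingResult].
#' @param truth The `truth` component of [simulatePeakTable()] output.
#' @param table Optional [PeakTable] whose `cluster_id` column carries the
#'   predicted clustering; when omitted the cluster agreement is skipped
#'   (`NA`).
#' @return A list with elements `trf`, `fragment`, `srf` (each
#'   precision/recall) and `rand_index`.
#' @export
scoreAgainstTruth <- function(result, truth, table = NULL) {
    at <- attributions(result)
    exp_at <- truth$expected_attribution
    if (!setequal(names(at), names(exp_at)))
        stop("feature universe mismatch between result and truth")
    exp_at <- exp_at[names(at)]
    out <- list(
        trf = .prf(names(at)[at == "TRF"], names(exp_at)[exp_at == "TRF"]),
        fragment = .prf(names(at)[at == "fragment"],
                        names(exp_at)[exp_at == "fragment"]),
        srf = .prf(names(at)[at == "SRF"], names(exp_at)[exp_at == "SRF"]))
    out$rand_index <- NA_real_
    if (!is.null(table)) {
        ids <- featureIds(table)
        pred <- clusterIds(table)[ids]
        exp_cl <- rep(NA_character_, length(ids))
        names(exp_cl) <- ids
        for (cl in names(truth$expected_clusters))
            exp_cl[truth$expected_clusters[[cl]]] <- cl
        ok <- !is.na(pred) & !is.na(exp_cl)
        if (sum(ok) >= 2L)
            out$rand_index <- .randIndex(pred[ok], exp_cl[ok])
    }
    out
}
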