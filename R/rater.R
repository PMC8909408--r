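#' @include AllClasses.R accessors.R adducts.R fragments.R
NULL

#' Rate every feature of a clustered peak table
#'
#' Applies the feature-rating rule cluster by cluster: adduct-correlation
#' flagging ([flagCluster()]) marks TRFs, the in-source fragment screen
#' ([screenFragments()]) removes features whose MS1 m/z recurs in a heavier
#' cluster mate's MS2, and the remainder are SRFs ([classifySrf()]).
#' Features the prefilters marked `interference` keep that attribution. Per
#' TRF correlation group the most intense member is selected as the
#' representative ([selectRepresentative()]); the final feature set is the
#' representatives plus all SRFs, ordered by retention time then m/z. The
#' result is deterministic for a fixed input and configuration, including
#' under row permutation of the input.
#'
#' @param table A clustered [PeakTable] (every non-interference feature must
#'   carry a `cluster_id`; run [clusterFeatures()] first otherwise).
#' @param rules adduct-correlation rules, see [defaultPositiveRules()].
#' @param fragmentTol fragment-screen tolerance in Da (default 0.05).
#' @param intensityMetric how "most intense" is measured:
#'   `"mean_biological"` (default), `"max_sample"` or `"mean_qc"`.
#' @param strict,strictRtTol,strictMinPearson passed to [flagCluster()].
#' @param ms2MinRelIntensity passed to [screenFragments()].
#' @return A [RatingResult].
#' @seealso [applyRating()] to write the result back into the table,
#'   [summarizeAttributions()] for the accounting.
#' @export
rateTable <- function(table, rules = defaultPositiveRules(),
                      fragmentTol = 0.05,
                      intensityMetric = c("mean_biological", "max_sample",
                                          "mean_qc"),
                      strict = FALSE, strictRtTol = 0.03,
                      strictMinPearson = 0.8, ms2MinRelIntensity = 0) {
    intensityMetric <- match.arg(intensityMetric)
    stopifnot(fragmentTol > 0)
    at_in <- attributions(table)
    active <- names(at_in)[at_in != "interference"]
    cid <- clusterIds(table)[active]
    if (anyNA(cid))
        stop("unclustered input: ", sum(is.na(cid)), " feature(s) without a ",
             "cluster_id; run clusterFeatures() (prefilter) first")
    clusters <- split(active, cid)

    att <- at_in
    att[active] <- NA_character_
    assignments <- list(); evidence <- list(); frag_calls <- list()
    groups <- list()
    for (cl in names(clusters)) {
        members <- clusters[[cl]]
        fl <- flagCluster(table, members, rules, strict = strict,
                          strictRtTol = strictRtTol,
                          strictMinPearson = strictMinPearson)
        trf <- fl$assignments$feature_id
        fc <- screenFragments(table, members, trfIds = trf,
                              tolerance = fragmentTol,
                              ms2MinRelIntensity = ms2MinRelIntensity)
        frag <- unique(fc$fragment_id)
        srf <- classifySrf(members, trf, frag)
        att[trf] <- "TRF"; att[frag] <- "fragment"; att[srf] <- "SRF"
        if (nrow(fl$assignments)) {
            fl$assignments$cluster_id <- cl
            assignments[[cl]] <- fl$assignments
            evidence[[cl]] <- fl$evidence
            groups[[cl]] <- split(fl$assignments$feature_id,
                                  fl$assignments$group)
        }
        if (nrow(fc)) frag_calls[[cl]] <- fc
    }
    stopifnot(!anyNA(att))

    # global group ids, deterministic: ordered by minimum member m/z
    all_groups <- unlist(unname(groups), recursive = FALSE, use.names = FALSE)
    if (length(all_groups)) {
        gmin <- vapply(all_groups, function(g) min(mz(table)[g]), 0)
        all_groups <- all_groups[order(gmin)]
        names(all_groups) <- .tokenSeries("G", length(all_groups))
    } else all_groups <- structure(list(), names = character())

    asg <- if (length(assignments)) do.call(rbind, unname(assignments)) else
        data.frame(feature_id = character(), adduct_label = character(),
                   group = integer(), cluster_id = character())
    gid_of <- character()
    for (g in names(all_groups)) gid_of[all_groups[[g]]] <- g
    asg$group_id <- unname(gid_of[asg$feature_id])
    asg <- asg[order(asg$group_id, mz(table)[asg$feature_id]),
               c("feature_id", "adduct_label", "group_id", "cluster_id")]
    rownames(asg) <- NULL
    ev <- if (length(evidence)) do.call(rbind, unname(evidence)) else
        data.frame(feature_id = character(), partner_id = character(),
                   rule = character(), error_da = numeric())
    ev <- ev[order(ev$feature_id, ev$partner_id), , drop = FALSE]
    rownames(ev) <- NULL
    fc_all <- if (length(frag_calls)) do.call(rbind, unname(frag_calls)) else
        data.frame(fragment_id = character(), owner_id = character(),
                   matched_ms2_mz = numeric(), error_da = numeric(),
                   primary = logical())
    fc_all <- fc_all[order(fc_all$fragment_id, fc_all$error_da,
                           fc_all$owner_id), , drop = FALSE]
    rownames(fc_all) <- NULL

    reps <- vapply(all_groups, selectRepresentative, "", table = table,
                   metric = intensityMetric)
    srf_ids <- names(att)[att == "SRF"]
    fin <- unique(c(unname(reps), srf_ids))
    fin <- fin[order(rt(table)[fin], mz(table)[fin], fin)]

    new("RatingResult", attributions = att, assignments = asg,
        evidence = ev, groups = all_groups,
        representatives = reps, fragment_calls = fc_all, final_ids = fin)
}

#' Select the most intense TRF of one correlation group
#'
#' Returns the group member maximising the intensity metric (default: mean
#' height over biological samples). Ties are broken deterministically by
#' lower m/z, then lexicographic feature id.
#'
#' @param group character vector of TRF feature ids (non-empty).
#' @param table The [PeakTable] the ids refer to.
#' @param metric `"mean_biological"`, `"max_sample"` or `"mean_qc"`.
#' @return A single feature id.
#' @export
selectRepresentative <- function(group, table,
                                 metric = c("mean_biological", "max_sample",
                                            "mean_qc")) {
    metric <- match.arg(metric)
    stopifnot(length(group) >= 1L)
    h <- heights(table)[group, , drop = FALSE]
    cols <- switch(metric,
                   mean_biological = biologicalSamples(table),
                   max_sample = colnames(h),
                   mean_qc = qcSamples(table))
    if (!length(cols))
        stop("no sample available for intensity metric '", metric, "'")
    score <- if (metric == "max_sample")
        apply(h[, cols, drop = FALSE], 1L, max)
    else rowMeans(h[, cols, drop = FALSE])
    ord <- order(-score, mz(table)[group], group)
    group[ord[1L]]
}

#' Write a RatingResult back into a PeakTable
#'
#' Fills the `attribution`, `adduct_label`, `group_id` and
#' `is_representative` feature columns from a [RatingResult], so the table
#' can be written with [writePeakTable()]. Upstream adduct labels that
#' disagree with the freshly computed flags are counted in the provenance
#' log (they are recorded but never trusted over the computed flags).
#'
#' @param table The [PeakTable] that was rated.
#' @param result The [RatingResult] from [rateTable()].
#' @return The annotated [PeakTable].
#' @export
applyRating <- function(table, result) {
    at <- attributions(result)
    idx <- match(names(at), featureIds(table))
    if (anyNA(idx))
        stop("rating refers to feature(s) absent from the table")
    rowData(table)$attribution[idx] <- unname(at)
    rowData(table)$adduct_label <- NA_character_
    rowData(table)$group_id <- NA_character_
    asg <- adductAssignments(result)
    if (nrow(asg)) {
        j <- match(asg$feature_id, featureIds(table))
        rowData(table)$adduct_label[j] <- asg$adduct_label
        rowData(table)$group_id[j] <- asg$group_id
    }
    rowData(table)$is_representative <-
        featureIds(table) %in% representatives(result)
    up <- rowData(table)$upstream_adduct
    disagree <- !is.na(up) & !is.na(rowData(table)$adduct_label) &
        up != rowData(table)$adduct_label
    line <- sprintf(
        "rating applied: %d TRF, %d SRF, %d fragment, %d interference",
        sum(at == "TRF"), sum(at == "SRF"), sum(at == "fragment"),
        sum(at == "interference"))
    if (any(disagree))
        line <- paste0(line, sprintf(
            "; %d upstream adduct label(s) disagree with computed flags",
            sum(disagree)))
    table <- .appendProvenance(table, line)
    validObject(table)
    table
}

#' Summarise an attribution accounting
#'
#' @param result A [RatingResult].
#' @return A list: per-category `counts`, `total`, `real_fraction`
#'   ((TRF + SRF) / total), `fragment_fraction`, `n_groups`,
#'   `final_table_size` (representatives + SRFs) and `empty` (flag set when
#'   the result covers no features; fractions are then reported as 0).
#' @export
summarizeAttributions <- function(result) {
    at <- attributions(result)
    total <- length(at)
    counts <- vapply(c("TRF", "SRF", "fragment", "interference"),
                     function(k) sum(at == k), 0L)
    real <- if (total) (counts[["TRF"]] + counts[["SRF"]]) / total else 0
    frag <- if (total) counts[["fragment"]] / total else 0
    list(counts = as.list(counts), total = total,
         real_fraction = real, fragment_fraction = frag,
         n_groups = length(trfGroups(result)),
         final_table_size = length(finalIds(result)),
         empty = total == 0L)
}
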