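#' @include AllClasses.R accessors.R
#' @importFrom stats cor sd median
#' @importFrom igraph graph_from_data_frame components V
NULL

#' Prefilter configuration
#'
#' Thresholds for the minimal upstream cleaning steps: blank filtering,
#' within-class RSD filtering and Pearson/RT feature clustering. The
#' clustering thresholds follow the common practice of the MS-CleanR family
#' of tools: features are linked when their biological-sample height vectors
#' have Pearson correlation at least `minPearson` (default 0.8) and their
#' retention times differ by at most `clusterRtTol` minutes (default 0.03).
#'
#' @param minBlankRatio A feature is kept when its maximum biological height
#'   is at least `minBlankRatio` times its mean blank height. `0` disables
#'   the filter. Default 0.8.
#' @param maxClassRsd A feature is kept when at least one biological class
#'   has within-class relative standard deviation (sd/mean of heights) at or
#'   below this fraction. Default 0.30.
#' @param minPearson Minimum Pearson correlation for a clustering edge, in
#'   `[-1, 1]`. Default 0.8.
#' @param clusterRtTol Maximum retention-time difference (minutes) for a
#'   clustering edge. Default 0.03.
#' @return A list of class `filterConfig`.
#' @export
filterConfig <- function(minBlankRatio = 0.8, maxClassRsd = 0.30,
                         minPearson = 0.8, clusterRtTol = 0.03) {
    stopifnot(is.numeric(minBlankRatio), minBlankRatio >= 0,
              is.numeric(maxClassRsd), maxClassRsd > 0,
              is.numeric(minPearson), minPearson >= -1, minPearson <= 1,
              is.numeric(clusterRtTol), clusterRtTol > 0)
    structure(list(minBlankRatio = minBlankRatio, maxClassRsd = maxClassRsd,
                   minPearson = minPearson, clusterRtTol = clusterRtTol),
              class = "filterConfig")
}

#' Normalise peak heights by an internal standard
#'
#' Divides every feature's height in sample `s` by the internal standard's
#' height in `s`, then rescales by the internal standard's median height over
#' biological samples so that magnitudes stay comparable. The internal
#' standard row itself is removed from the table. Blank samples in which the
#' standard was not detected are left unscaled (with a provenance note);
#' a missing standard in any biological or QC sample is an error.
#'
#' @param table A [PeakTable].
#' @param isFeatureId feature id of the spiked internal standard.
#' @return The normalised [PeakTable] without the internal-standard row.
#' @export
normalizeInternalStandard <- function(table, isFeatureId) {
    fid <- featureIds(table)
    if (!isFeatureId %in% fid)
        stop("internal standard '", isFeatureId, "' not present in the table")
    h <- heights(table)
    is_h <- h[isFeatureId, ]
    must <- c(biologicalSamples(table), qcSamples(table))
    bad <- must[is_h[must] <= 0]
    if (length(bad))
        stop("internal standard missing (height 0) in sample(s): ",
             paste(bad, collapse = ", "))
    scale_to <- median(is_h[biologicalSamples(table)])
    factors <- ifelse(is_h > 0, scale_to / is_h, 1)
    h2 <- sweep(h, 2L, factors, `*`)
    out <- table[fid != isFeatureId, ]
    assay(out, "height") <- h2[fid != isFeatureId, , drop = FALSE]
    skipped <- names(is_h)[is_h <= 0]
    out <- .appendProvenance(out, sprintf(
        "normalized by internal standard %s (median %.4g)%s", isFeatureId,
        scale_to,
        if (length(skipped)) paste0("; unscaled sample(s): ",
                                    paste(skipped, collapse = ",")) else ""))
    validObject(out)
    out
}

#' Blank filter
#'
#' Marks as `interference` every feature whose maximum height over biological
#' samples falls below `minBlankRatio` times its mean height over blank
#' samples; features absent from the blanks are always retained. Marked rows
#' are kept in the table for auditability (downstream stages and the `final`
#' writer exclude them).
#'
#' @param table A [PeakTable].
#' @param cfg A [filterConfig()].
#' @return The [PeakTable] with failing features marked `interference`.
#' @export
blankFilter <- function(table, cfg = filterConfig()) {
    blanks <- blankSamples(table)
    if (!length(blanks)) {
        warning("no blank sample declared; blank filter skipped", call. = FALSE)
        return(.appendProvenance(table, "blank filter skipped (no blank)"))
    }
    h <- heights(table)
    bio <- biologicalSamples(table)
    blank_mean <- rowMeans(h[, blanks, drop = FALSE])
    bio_max <- apply(h[, bio, drop = FALSE], 1L, max)
    fail <- bio_max < cfg$minBlankRatio * blank_mean
    fail <- fail & attributions(table) == "unrated"
    if (any(fail)) {
        at <- attributions(table)
        at[fail] <- "interference"
        attributions(table) <- at
    }
    .appendProvenance(table, sprintf(
        "blank filter (ratio %.3g): %d of %d features marked interference",
        cfg$minBlankRatio, sum(fail), nrow(table)))
}

.classRsd <- function(v) {
    m <- mean(v)
    if (m == 0) return(Inf)
    sd(v) / m
}

#' Within-class RSD filter
#'
#' Marks as `interference` every feature whose within-class relative standard
#' deviation (sd/mean of heights among replicates of one biological class)
#' exceeds `maxClassRsd` in every class; a feature stable in at least one
#' class is retained. Classes with fewer than two replicates are skipped;
#' when no class has two replicates the filter is a no-op with a warning.
#'
#' @inheritParams blankFilter
#' @return The [PeakTable] with unstable features marked `interference`.
#' @export
rsdFilter <- function(table, cfg = filterConfig()) {
    cd <- colData(table)
    bio <- cd$sample_id[cd$role == "biological"]
    classes <- split(bio, cd$class_label[match(bio, cd$sample_id)])
    classes <- classes[lengths(classes) >= 2L]
    if (!length(classes)) {
        warning("no biological class with >= 2 replicates; RSD filter skipped",
                call. = FALSE)
        return(.appendProvenance(table, "RSD filter skipped (no replicates)"))
    }
    h <- heights(table)
    best <- apply(vapply(classes, function(s)
        apply(h[, s, drop = FALSE], 1L, .classRsd),
        numeric(nrow(table))), 1L, min)
    fail <- best > cfg$maxClassRsd
    fail <- fail & attributions(table) == "unrated"
    if (any(fail)) {
        at <- attributions(table)
        at[fail] <- "interference"
        attributions(table) <- at
    }
    .appendProvenance(table, sprintf(
        "RSD filter (max %.3g, %d class(es)): %d of %d features marked interference",
        cfg$maxClassRsd, length(classes), sum(fail), nrow(table)))
}

#' Pearson / retention-time feature clustering
#'
#' Builds an undirected graph on the (non-interference) features with an edge
#' whenever two features co-elute (`|rt_i - rt_j| <= clusterRtTol`) and their
#' biological-sample height vectors correlate (Pearson `>= minPearson`);
#' clusters are the connected components. Every feature, singletons included,
#' receives a cluster id; ids are deterministic, ordered by the lowest member
#' m/z, so the partition is invariant under row permutation of the input.
#' Constant-height features (Pearson undefined) are treated as uncorrelated
#' with everything and end up singletons.
#'
#' @inheritParams blankFilter
#' @return The [PeakTable] with `cluster_id` filled in; the partition itself
#'   is available through [featureClusters()].
#' @export
clusterFeatures <- function(table, cfg = filterConfig()) {
    bio <- biologicalSamples(table)
    if (length(bio) < 3L)
        stop("clustering needs >= 3 biological samples (Pearson on fewer is meaningless)")
    keep <- attributions(table) != "interference"
    fid <- featureIds(table)[keep]
    n <- length(fid)
    rowData(table)$cluster_id <- NA_character_
    if (n == 0L)
        return(.appendProvenance(table, "clustering: no features"))
    h <- heights(table)[fid, bio, drop = FALSE]
    rts <- rt(table)[fid]
    const <- apply(h, 1L, function(v) sd(v) == 0)
    ord <- order(rts)
    from <- integer(); to <- integer()
    # RT-window sweep keeps the pair loop near-linear on sorted RTs
    for (a in seq_len(n)) {
        i <- ord[a]
        b <- a + 1L
        while (b <= n && rts[ord[b]] - rts[i] <= cfg$clusterRtTol) {
            j <- ord[b]
            if (!const[i] && !const[j] &&
                cor(h[i, ], h[j, ]) >= cfg$minPearson) {
                from <- c(from, i); to <- c(to, j)
            }
            b <- b + 1L
        }
    }
    g <- igraph::graph_from_data_frame(
        data.frame(from = fid[from], to = fid[to]),
        directed = FALSE, vertices = fid)
    comp <- igraph::components(g)$membership[fid]
    # deterministic ids ordered by lowest member m/z
    mzs <- mz(table)[fid]
    comp_min_mz <- tapply(mzs, comp, min)
    rank <- rank(comp_min_mz, ties.method = "first")
    ids <- .tokenSeries("CL", length(comp_min_mz))
    cl <- ids[rank[as.character(comp)]]
    rowData(table)$cluster_id[match(fid, featureIds(table))] <- cl
    if (any(const))
        table <- .appendProvenance(table, sprintf(
            "clustering: %d constant-height feature(s) treated as singletons",
            sum(const)))
    .appendProvenance(table, sprintf(
        "clustered %d features into %d cluster(s) (r >= %.2f, dRT <= %.3g min)",
        n, length(comp_min_mz), cfg$minPearson, cfg$clusterRtTol))
}
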