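#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment rowData rowData<-
#'   colData colData<- assay assays
NULL

.ATTRIBUTION_LEVELS <- c("unrated", "TRF", "SRF", "fragment", "interference")
.SAMPLE_ROLES <- c("biological", "blank", "qc")
.POLARITIES <- c("positive", "negative")

#' PeakTable: an aligned LC-MS feature table
#'
#' `PeakTable` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with the structure of an aligned untargeted LC-MS peak table as exported by
#' MS-DIAL and downstream cleaning tools: one row per feature (average m/z,
#' average retention time, optional cluster id, optional upstream adduct
#' label, an MS2 spectrum, and an evolving attribution), one column per sample
#' (with a role: biological, blank or QC, and a biological class label), and a
#' single `"height"` assay of chromatographic peak heights.
#'
#' Required `rowData` columns: `feature_id`, `mz`, `rt`, `cluster_id`,
#' `upstream_adduct`, `attribution`, `adduct_label`, `group_id`, and the
#' list-column `ms2` holding two-column `(mz, intensity)` matrices sorted
#' ascending by m/z. Required `colData` columns: `sample_id`, `role`,
#' `class_label`. `metadata()` carries `polarity` and a `provenance` character
#' vector logging applied operations.
#'
#' @slot .. see [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class].
#' @seealso [PeakTable()] for construction, [readAlignmentTable()] to read the
#'   MS-DIAL export dialect.
#' @export
setClass("PeakTable", contains = "SummarizedExperiment")

.validSpectrum <- function(s) {
    if (!is.matrix(s) || !is.numeric(s) || ncol(s) != 2L)
        return("each MS2 spectrum must be a numeric matrix with 2 columns (mz, intensity)")
    if (nrow(s) == 0L) return(TRUE)
    if (anyNA(s)) return("MS2 spectra must not contain NA")
    if (any(s[, 1L] <= 0)) return("MS2 peak m/z values must be > 0")
    if (any(s[, 2L] < 0)) return("MS2 peak intensities must be >= 0")
    if (is.unsorted(s[, 1L])) return("MS2 peaks must be sorted ascending by m/z")
    TRUE
}

setValidity("PeakTable", function(object) {
    msg <- character()
    rd <- rowData(object)
    cd <- colData(object)
    need_rd <- c("feature_id", "mz", "rt", "cluster_id", "upstream_adduct",
                 "attribution", "adduct_label", "group_id", "ms2")
    miss <- setdiff(need_rd, colnames(rd))
    if (length(miss))
        return(paste("missing rowData column(s):", paste(miss, collapse = ", ")))
    need_cd <- c("sample_id", "role", "class_label")
    miss <- setdiff(need_cd, colnames(cd))
    if (length(miss))
        return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(rd$feature_id))
        msg <- c(msg, "feature_id values must be unique")
    if (nrow(object) > 0L) {
        if (!identical(rownames(object), as.character(rd$feature_id)))
            msg <- c(msg, "rownames must equal feature_id")
        if (any(!is.finite(rd$mz)) || any(rd$mz <= 0))
            msg <- c(msg, "mz must be finite and > 0")
        if (any(!is.finite(rd$rt)) || any(rd$rt < 0))
            msg <- c(msg, "rt must be finite and >= 0")
        if (!all(rd$attribution %in% .ATTRIBUTION_LEVELS))
            msg <- c(msg, sprintf("attribution must be one of %s",
                                  paste(.ATTRIBUTION_LEVELS, collapse = ", ")))
        bad <- vapply(rd$ms2, function(s) !isTRUE(.validSpectrum(s)), logical(1L))
        if (any(bad))
            msg <- c(msg, sprintf("invalid MS2 spectrum for feature(s) %s",
                                  paste(head(rd$feature_id[bad], 3L), collapse = ", ")))
    }
    if (ncol(object) > 0L) {
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "sample_id values must be unique")
        if (!all(cd$role %in% .SAMPLE_ROLES))
            msg <- c(msg, sprintf("sample role must be one of %s",
                                  paste(.SAMPLE_ROLES, collapse = ", ")))
        h <- assay(object, "height")
        if (anyNA(h) || any(h < 0))
            msg <- c(msg, "heights must be non-negative and non-missing")
    }
    if (!"height" %in% names(assays(object)))
        msg <- c(msg, "assay 'height' is required")
    pol <- metadata(object)$polarity
    if (is.null(pol) || !pol %in% .POLARITIES)
        msg <- c(msg, "metadata()$polarity must be 'positive' or 'negative'")
    if (length(msg)) msg else TRUE
})

#' Construct a PeakTable
#'
#' @param features `data.frame` with at least `feature_id`, `mz`, `rt`;
#'   optionally `cluster_id`, `upstream_adduct`, `attribution`,
#'   `adduct_label`, `group_id`.
#' @param heights numeric matrix, features x samples; row order must match
#'   `features`. A 0-column matrix is allowed.
#' @param samples `data.frame` with `sample_id` and optionally `role`
#'   (`"biological"`, `"blank"`, `"qc"`; default biological) and
#'   `class_label` (default `sample_id`).
#' @param spectra list of spectra (one per feature), each a two-column
#'   numeric matrix `(mz, intensity)`; `NULL` entries become empty spectra.
#' @param polarity `"positive"` or `"negative"`.
#' @param provenance character vector of log lines.
#' @return A [PeakTable] object.
#' @examples
#' pt <- PeakTable(
#'   features = data.frame(feature_id = c("F1", "F2"),
#'                         mz = c(301.0073, 322.9892), rt = c(5.1, 5.1)),
#'   heights = matrix(c(100, 200, 50, 80), nrow = 2,
#'                    dimnames = list(NULL, c("S1", "S2"))),
#'   samples = data.frame(sample_id = c("S1", "S2")))
#' pt
#' @export
PeakTable <- function(features, heights = NULL, samples = NULL,
                      spectra = NULL, polarity = c("positive", "negative"),
                      provenance = character()) {
    polarity <- match.arg(polarity)
    features <- as.data.frame(features)
    stopifnot(all(c("feature_id", "mz", "rt") %in% colnames(features)))
    n <- nrow(features)
    fid <- as.character(features$feature_id)
    if (anyDuplicated(fid))
        stop("duplicate feature_id: ",
             paste(unique(fid[duplicated(fid)]), collapse = ", "))

    optChr <- function(col) {
        if (col %in% colnames(features)) {
            v <- as.character(features[[col]])
            v[is.na(v)] <- NA_character_
            v
        } else rep(NA_character_, n)
    }
    attribution <- if ("attribution" %in% colnames(features)) {
        v <- as.character(features$attribution)
        v[is.na(v) | v == ""] <- "unrated"
        v
    } else rep("unrated", n)

    if (is.null(samples)) samples <- data.frame(sample_id = character())
    samples <- as.data.frame(samples)
    if (!"sample_id" %in% colnames(samples))
        stop("samples needs a sample_id column")
    samples$sample_id <- as.character(samples$sample_id)
    if (!"role" %in% colnames(samples)) samples$role <- "biological"
    if (!"class_label" %in% colnames(samples))
        samples$class_label <- samples$sample_id
    ns <- nrow(samples)

    if (is.null(heights)) {
        heights <- matrix(0, nrow = n, ncol = ns,
                          dimnames = list(fid, samples$sample_id))
    } else {
        heights <- as.matrix(heights)
        if (nrow(heights) != n)
            stop("heights must have one row per feature")
        if (is.null(colnames(heights)))
            colnames(heights) <- samples$sample_id
        extra <- setdiff(colnames(heights), samples$sample_id)
        if (length(extra))
            stop("height column(s) with no declared sample: ",
                 paste(extra, collapse = ", "))
        heights <- heights[, samples$sample_id, drop = FALSE]
        rownames(heights) <- fid
    }

    if (is.null(spectra)) spectra <- vector("list", n)
    if (length(spectra) != n) stop("spectra must have one entry per feature")
    spectra <- lapply(spectra, .asSpectrum)

    rd <- DataFrame(feature_id = fid,
                    mz = as.numeric(features$mz),
                    rt = as.numeric(features$rt),
                    cluster_id = optChr("cluster_id"),
                    upstream_adduct = optChr("upstream_adduct"),
                    attribution = attribution,
                    adduct_label = optChr("adduct_label"),
                    group_id = optChr("group_id"))
    rd$ms2 <- spectra
    rownames(rd) <- fid
    cd <- DataFrame(sample_id = samples$sample_id,
                    role = as.character(samples$role),
                    class_label = as.character(samples$class_label),
                    row.names = samples$sample_id)
    se <- SummarizedExperiment(assays = SimpleList(height = heights),
                               rowData = rd, colData = cd)
    metadata(se)$polarity <- polarity
    metadata(se)$provenance <- as.character(provenance)
    new("PeakTable", se)
}

#' RatingResult: the outcome of feature rating
#'
#' The final partition of the features of a [PeakTable] into TRF / SRF /
#' in-source fragment / filtered interference, together with the TRF adduct
#' correlation groups, the selected per-group representatives, the
#' evidence-carrying adduct assignments and the fragment-call audit trail.
#'
#' @slot attributions named character; one of `"TRF"`, `"SRF"`, `"fragment"`,
#'   `"interference"` per input feature.
#' @slot assignments `data.frame` (`feature_id`, `adduct_label`, `group_id`)
#'   for TRFs.
#' @slot evidence `data.frame` (`feature_id`, `partner_id`, `rule`,
#'   `error_da`) — every accepted adduct-correlation edge, both directions.
#' @slot groups named list: `group_id` -> character vector of TRF feature ids.
#' @slot representatives named character: `group_id` -> most intense member.
#' @slot fragment_calls `data.frame` (`fragment_id`, `owner_id`,
#'   `matched_ms2_mz`, `error_da`, `primary`).
#' @slot final_ids character: representatives plus SRFs, ordered by retention
#'   time then m/z.
#' @seealso [rateTable()], [summarizeAttributions()]
#' @export
setClass("RatingResult",
         representation(attributions = "character",
                        assignments = "data.frame",
                        evidence = "data.frame",
                        groups = "list",
                        representatives = "character",
                        fragment_calls = "data.frame",
                        final_ids = "character"))

setValidity("RatingResult", function(object) {
    msg <- character()
    at <- object@attributions
    if (length(at) && (is.null(names(at)) || anyDuplicated(names(at))))
        return("attributions must be uniquely named by feature_id")
    if (!all(at %in% c("TRF", "SRF", "fragment", "interference")))
        msg <- c(msg, "attributions must be TRF, SRF, fragment or interference")
    gs <- object@groups
    reps <- object@representatives
    if (!setequal(names(reps), names(gs)))
        msg <- c(msg, "representatives must be named by group_id")
    for (g in names(reps))
        if (!reps[[g]] %in% gs[[g]])
            msg <- c(msg, sprintf("representative of %s is not a member", g))
    if (length(unlist(gs)) &&
        !all(at[unlist(gs)] == "TRF"))
        msg <- c(msg, "group members must be TRFs")
    if (anyDuplicated(object@final_ids))
        msg <- c(msg, "final_ids must be unique")
    if (length(msg)) msg else TRUE
})
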