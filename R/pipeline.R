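#' @include AllClasses.R io.R prefilter.R rater.R
#' @importFrom jsonlite write_json
NULL

#' End-to-end feature-rating pipeline
#'
#' Runs the whole workflow on an aligned peak table: read (when `input` is a
#' path), optional internal-standard normalisation, blank and within-class
#' RSD filters, Pearson/RT clustering (only when the input carries no
#' cluster ids, or when `recluster = TRUE` — upstream clusters are honoured
#' otherwise), feature rating, and writes the full annotated table, the
#' final curated table, the attribution report, the fragment-call audit and
#' a JSON run manifest into `outputDir`. The manifest's count ledger
#' satisfies `input = TRF + SRF + fragment + interference`. On failure,
#' partial outputs are removed.
#'
#' @param input A [PeakTable] or a path readable by [readAlignmentTable()].
#' @param outputDir Directory for artifacts (created if needed).
#' @param rules Adduct-correlation rules; default the six positive-mode
#'   correlations ([defaultPositiveRules()]) at `adductTol`.
#' @param filterCfg A [filterConfig()].
#' @param adductTol Adduct-flagging tolerance in Da (default 0.01); used to
#'   build the default rules (ignored when `rules` is given).
#' @param fragmentTol Fragment-removal tolerance in Da (default 0.05).
#' @param isFeatureId Optional internal-standard feature id for
#'   normalisation.
#' @param normalize,runBlankFilter,runRsdFilter stage switches.
#' @param recluster Force re-clustering even when the input carries cluster
#'   ids.
#' @param strict Strict flagging mode (per-edge co-elution/correlation
#'   check), see [flagCluster()].
#' @param intensityMetric Representative-selection metric, see
#'   [rateTable()].
#' @param samples,polarity Passed to [readAlignmentTable()] for path input.
#' @return Invisibly, a list: `table` (annotated [PeakTable]), `result`
#'   ([RatingResult]), `summary`, `manifest` (the manifest also written as
#'   JSON).
#' @export
runPipeline <- function(input, outputDir,
                        rules = NULL, filterCfg = filterConfig(),
                        adductTol = 0.01, fragmentTol = 0.05,
                        isFeatureId = NULL, normalize = !is.null(isFeatureId),
                        runBlankFilter = TRUE, runRsdFilter = TRUE,
                        recluster = FALSE, strict = FALSE,
                        intensityMetric = "mean_biological",
                        samples = NULL, polarity = "positive") {
    if (!is.numeric(adductTol) || adductTol <= 0)
        stop("config error: adductTol must be > 0")
    if (!is.numeric(fragmentTol) || fragmentTol <= 0)
        stop("config error: fragmentTol must be > 0")
    if (is.null(rules)) rules <- defaultPositiveRules(tolerance = adductTol)
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(outputDir, c("peak_table_full.csv",
                                    "peak_table_final.csv",
                                    "attribution_report.csv",
                                    "fragment_calls.csv",
                                    "manifest.json"))
    names(paths) <- c("full", "final", "report", "fragments", "manifest")
    ok <- FALSE
    on.exit(if (!ok) unlink(paths[file.exists(paths)]))

    counts <- list()
    note <- function(stage, table) {
        at <- attributions(table)
        counts[[stage]] <<- list(
            features = length(at),
            active = sum(at != "interference"),
            interference = sum(at == "interference"))
        message(sprintf("[peakRating] %s: %d feature(s), %d active",
                        stage, length(at), sum(at != "interference")))
    }

    pt <- if (is.character(input))
        readAlignmentTable(input, samples = samples, polarity = polarity)
    else input
    stopifnot(is(pt, "PeakTable"))
    note("input", pt)

    if (normalize) {
        if (is.null(isFeatureId))
            stop("config error: normalize = TRUE needs isFeatureId")
        pt <- normalizeInternalStandard(pt, isFeatureId)
        note("normalized", pt)
    }
    if (runBlankFilter) {
        pt <- blankFilter(pt, filterCfg)
        note("blank_filter", pt)
    }
    if (runRsdFilter) {
        pt <- rsdFilter(pt, filterCfg)
        note("rsd_filter", pt)
    }
    need_cluster <- recluster || anyNA(clusterIds(pt)[
        attributions(pt) != "interference"])
    if (need_cluster) {
        pt <- clusterFeatures(pt, filterCfg)
        note("clustered", pt)
    }

    result <- rateTable(pt, rules = rules, fragmentTol = fragmentTol,
                        intensityMetric = intensityMetric, strict = strict)
    pt <- applyRating(pt, result)
    note("rated", pt)

    smry <- summarizeAttributions(result)
    writePeakTable(pt, paths["full"], kind = "full")
    writePeakTable(pt, paths["final"], kind = "final")
    writePeakTable(pt, paths["report"], kind = "report")
    data.table::fwrite(fragmentCalls(result), paths["fragments"])

    manifest <- list(
        package = "peakRating",
        version = as.character(utils::packageVersion("peakRating")),
        config = list(adduct_rules = rules, filter = unclass(filterCfg),
                      fragment_tol = fragmentTol, strict = strict,
                      intensity_metric = intensityMetric,
                      normalized = normalize, recluster = recluster),
        stage_counts = counts,
        summary = smry,
        provenance = provenance(pt))
    write_json(manifest, paths["manifest"], auto_unbox = TRUE, digits = NA,
               pretty = TRUE)
    ok <- TRUE
    invisible(list(table = pt, result = result, summary = smry,
                   manifest = manifest, paths = paths))
}
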