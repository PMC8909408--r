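#' @include AllClasses.R accessors.R
#' @importFrom data.table fread fwrite
NULL

#' Parse an MS-DIAL style spectrum string
#'
#' MS-DIAL serialises an MS2 spectrum into one table cell as
#' whitespace-separated `mz:intensity` pairs (semicolons are tolerated as
#' separators too). The parser is total: any malformed token is skipped with
#' a warning, and arbitrary garbage yields an empty spectrum rather than an
#' error. Peaks are returned sorted ascending by m/z.
#'
#' @param text A character scalar (NA allowed).
#' @return A two-column numeric matrix `(mz, intensity)`.
#' @examples
#' parseSpectrumString("121.0295:300 93.0346:120")
#' parseSpectrumString("")              # empty spectrum
#' @export
parseSpectrumString <- function(text) {
    if (length(text) != 1L) stop("text must be a single string")
    if (is.na(text) || !nzchar(trimws(text))) return(.emptySpectrum())
    tokens <- strsplit(trimws(text), "[[:space:];]+")[[1L]]
    tokens <- tokens[nzchar(tokens)]
    parts <- strsplit(tokens, ":", fixed = TRUE)
    ok <- lengths(parts) == 2L
    mzv <- rep(NA_real_, length(tokens))
    iv <- rep(NA_real_, length(tokens))
    if (any(ok)) {
        mzv[ok] <- suppressWarnings(as.numeric(vapply(parts[ok], `[`, "", 1L)))
        iv[ok] <- suppressWarnings(as.numeric(vapply(parts[ok], `[`, "", 2L)))
    }
    good <- ok & is.finite(mzv) & is.finite(iv) & mzv > 0 & iv >= 0
    if (any(!good))
        warning(sum(!good), " malformed spectrum token(s) skipped: ",
                paste(head(tokens[!good], 3L), collapse = " "), call. = FALSE)
    if (!any(good)) return(.emptySpectrum())
    .asSpectrum(cbind(mzv[good], iv[good]))
}

#' Serialise a spectrum back to the MS-DIAL string encoding
#'
#' @param s A spectrum matrix as returned by [parseSpectrumString()].
#' @return A character scalar; `""` for an empty spectrum.
#' @export
formatSpectrumString <- function(s) {
    s <- .asSpectrum(s)
    if (nrow(s) == 0L) return("")
    paste(sprintf("%s:%s", format(s[, 1L], trim = TRUE, scientific = FALSE),
                  format(s[, 2L], trim = TRUE, scientific = FALSE)),
          collapse = " ")
}

# normalise a header for alias matching: case and punctuation insensitive
.normHeader <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Default column aliases for the MS-DIAL / MS-CleanR export dialect
#'
#' Both tools are chained upstream of this package and print different
#' headers for the same quantities; the reader resolves required columns
#' through this (user-extensible) alias map.
#'
#' @return Named list of character vectors of accepted header spellings.
#' @export
defaultColumnAliases <- function() {
    list(feature_id = c("Alignment ID", "Alignment.ID", "feature_id", "id",
                        "Feature ID", "Peak ID"),
         mz = c("Average Mz", "Average.Mz", "Average m/z", "mz",
                "Average Mz after MS-CleanR processing"),
         rt = c("Average Rt(min)", "Average.Rt.min.", "Average Rt (min)",
                "rt", "RT (min)", "Average RT(min)"),
         ms2 = c("MS/MS spectrum", "MS.MS.spectrum", "MSMS spectrum", "ms2"),
         cluster_id = c("cluster_id", "Cluster ID", "cluster", "Cluster.ID"),
         upstream_adduct = c("Adduct type", "Adduct.type", "upstream_adduct",
                             "Adduct ion name"),
         attribution = c("attribution"),
         adduct_label = c("adduct_label"),
         group_id = c("group_id"))
}

.sniffSep <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "csv") return(",")
    if (ext %in% c("tsv", "tab", "txt")) return("\t")
    line <- readLines(path, n = 1L, warn = FALSE)
    nt <- lengths(regmatches(line, gregexpr("\t", line)))
    nc <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
    if (nt > 0L && nc == 0L) return("\t")
    if (nc > 0L && nt == 0L) return(",")
    stop("cannot determine the delimiter of '", path,
         "': use a .csv or .tsv extension", call. = FALSE)
}

.inferRole <- function(sample_id) {
    low <- tolower(sample_id)
    ifelse(grepl("blank", low), "blank",
           ifelse(grepl("^qc|qc$|pool", low), "qc", "biological"))
}

.inferClass <- function(sample_id) sub("[._-]?[0-9]+$", "", sample_id)

#' Read an aligned peak table in the MS-DIAL / MS-CleanR export dialect
#'
#' Reads a CSV/TSV alignment export: one row per feature with an id, average
#' m/z, average retention time, optionally a cluster id, an upstream adduct
#' label and an MS2 spectrum string, plus one numeric height column per
#' sample. Row order is preserved. Unparseable MS2 cells become empty spectra
#' with a warning, never an error.
#'
#' @param path Path to a `.csv` / `.tsv` file.
#' @param samples Optional `data.frame` (`sample_id`, `role`, `class_label`)
#'   declaring the sample design. When omitted, every numeric column not
#'   matched by the alias map is taken as a sample; roles are inferred from
#'   the name (`blank`/`qc` substrings) and the class label is the name with
#'   any trailing replicate number stripped.
#' @param polarity Ionisation mode of the acquisition.
#' @param aliases Column alias map, see [defaultColumnAliases()]. Entries
#'   given here are appended in front of the defaults.
#' @param sep Field delimiter; default: sniffed from extension then content.
#' @return A [PeakTable].
#' @export
readAlignmentTable <- function(path, samples = NULL,
                               polarity = c("positive", "negative"),
                               aliases = list(), sep = NULL) {
    polarity <- match.arg(polarity)
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L)
        stop("peak-table format error: '", path, "' is empty", call. = FALSE)
    if (is.null(sep)) sep <- .sniffSep(path)
    amap <- defaultColumnAliases()
    for (nm in names(aliases)) amap[[nm]] <- c(aliases[[nm]], amap[[nm]])

    dt <- fread(path, sep = sep, header = TRUE, data.table = FALSE)
    if (nrow(dt) == 0L)
        stop("peak-table format error: '", path, "' has no data rows",
             call. = FALSE)
    hdr <- .normHeader(colnames(dt))
    resolve <- function(field) {
        hit <- match(.normHeader(amap[[field]]), hdr)
        hit <- hit[!is.na(hit)]
        if (length(hit)) colnames(dt)[hit[1L]] else NA_character_
    }
    required <- c("feature_id", "mz", "rt")
    cols <- vapply(names(amap), resolve, "")
    miss <- required[is.na(cols[required])]
    if (length(miss))
        stop("peak-table format error: missing required column(s): ",
             paste(miss, collapse = ", "),
             " (accepted spellings: ",
             paste(unlist(amap[miss]), collapse = "; "), ")", call. = FALSE)

    fid <- as.character(dt[[cols["feature_id"]]])
    if (anyDuplicated(fid))
        stop("peak-table validation error: duplicate feature id(s): ",
             paste(unique(fid[duplicated(fid)]), collapse = ", "),
             call. = FALSE)
    features <- data.frame(feature_id = fid,
                           mz = as.numeric(dt[[cols["mz"]]]),
                           rt = as.numeric(dt[[cols["rt"]]]))
    for (fld in c("cluster_id", "upstream_adduct", "attribution",
                  "adduct_label", "group_id"))
        if (!is.na(cols[fld])) {
            v <- as.character(dt[[cols[fld]]])
            v[v == ""] <- NA_character_
            features[[fld]] <- v
        }

    spectra <- NULL
    if (!is.na(cols["ms2"])) {
        raw <- as.character(dt[[cols["ms2"]]])
        raw[is.na(raw)] <- ""
        spectra <- lapply(raw, function(s)
            tryCatch(parseSpectrumString(s), error = function(e) {
                warning("unparseable MS2 cell replaced by empty spectrum",
                        call. = FALSE)
                .emptySpectrum()
            }))
    }

    known <- stats::na.omit(cols)
    rest <- setdiff(colnames(dt), known)
    if (is.null(samples)) {
        numeric_rest <- rest[vapply(dt[rest], is.numeric, logical(1L))]
        samples <- data.frame(sample_id = numeric_rest,
                              role = .inferRole(numeric_rest),
                              class_label = .inferClass(numeric_rest))
    } else {
        samples <- as.data.frame(samples)
        miss_s <- setdiff(samples$sample_id, rest)
        if (length(miss_s))
            stop("peak-table format error: declared sample column(s) absent: ",
                 paste(miss_s, collapse = ", "), call. = FALSE)
    }
    hm <- as.matrix(dt[, samples$sample_id, drop = FALSE])
    if (length(hm)) {
        storage.mode(hm) <- "double"
        hm[is.na(hm)] <- 0
    }
    pt <- PeakTable(features = features, heights = hm, samples = samples,
                    spectra = spectra, polarity = polarity,
                    provenance = sprintf("read %d features x %d samples from %s",
                                         nrow(features), nrow(samples),
                                         basename(path)))
    pt
}

#' Write a PeakTable (full, final or report form)
#'
#' `kind = "full"` writes every feature with its attribution, adduct label,
#' group id and representative flag appended; `kind = "final"` writes only
#' the curated final set (per-group most intense TRFs plus SRFs), ordered by
#' retention time then m/z; `kind = "report"` writes per-category attribution
#' counts. Reading a `full` file back with [readAlignmentTable()] restores
#' feature id, m/z, RT, cluster id and attribution exactly.
#'
#' @param table A [PeakTable] (for `"final"`, after [applyRating()]).
#' @param path Output path (`.csv` or `.tsv` picks the delimiter).
#' @param kind `"full"`, `"final"` or `"report"`.
#' @return Invisibly, the path.
#' @export
writePeakTable <- function(table, path, kind = c("full", "final", "report")) {
    kind <- match.arg(kind)
    sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
    rd <- rowData(table)
    if (kind == "report") {
        at <- factor(rd$attribution, levels = .ATTRIBUTION_LEVELS)
        counts <- as.data.frame(table(attribution = at),
                                responseName = "count")
        out <- rbind(counts, data.frame(attribution = "total",
                                        count = nrow(table)))
        fwrite(out, path, sep = sep)
        return(invisible(path))
    }
    df <- data.frame(feature_id = rd$feature_id,
                     mz = rd$mz, rt = rd$rt,
                     cluster_id = rd$cluster_id,
                     upstream_adduct = rd$upstream_adduct,
                     attribution = rd$attribution,
                     adduct_label = rd$adduct_label,
                     group_id = rd$group_id,
                     is_representative =
                         if ("is_representative" %in% colnames(rd))
                             rd$is_representative else FALSE,
                     ms2 = vapply(as.list(rd$ms2), formatSpectrumString, ""))
    h <- heights(table)
    if (ncol(h)) df <- cbind(df, as.data.frame(h, check.names = FALSE))
    if (kind == "final") {
        keep <- df$is_representative | df$attribution == "SRF"
        df <- df[keep, , drop = FALSE]
        df <- df[order(df$rt, df$mz, df$feature_id), , drop = FALSE]
    }
    fwrite(df, path, sep = sep, na = "")
    invisible(path)
}

#' Export per-feature MS2 spectra as an MSP library
#'
#' One record per feature carrying an MS2 spectrum: `NAME` = feature id,
#' `PRECURSORMZ` = MS1 m/z, `RETENTIONTIME` = RT (min), `Num Peaks` and the
#' peak list.
#'
#' @param table A [PeakTable].
#' @param path Output `.msp` path.
#' @param skipEmpty drop features with no MS2 (default `TRUE`).
#' @return Invisibly, the number of records written.
#' @export
writeMsp <- function(table, path, skipEmpty = TRUE) {
    rd <- rowData(table)
    con <- file(path, "w")
    on.exit(close(con))
    n <- 0L
    for (i in seq_len(nrow(table))) {
        s <- rd$ms2[[i]]
        if (skipEmpty && nrow(s) == 0L) next
        writeLines(c(sprintf("NAME: %s", rd$feature_id[i]),
                     sprintf("PRECURSORMZ: %.4f", rd$mz[i]),
                     sprintf("RETENTIONTIME: %.2f", rd$rt[i]),
                     sprintf("Num Peaks: %d", nrow(s)),
                     if (nrow(s)) sprintf("%g\t%g", s[, 1L], s[, 2L]),
                     ""), con)
        n <- n + 1L
    }
    invisible(n)
}
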