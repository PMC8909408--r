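.emptySpectrum <- function()
    matrix(numeric(), ncol = 2L, dimnames = list(NULL, c("mz", "intensity")))

# coerce anything reasonable (NULL, 2-col matrix, data.frame) to a canonical
# spectrum matrix, sorted ascending by m/z
.asSpectrum <- function(s) {
    if (is.null(s) || (is.atomic(s) && length(s) == 0L)) return(.emptySpectrum())
    if (is.data.frame(s)) s <- as.matrix(s)
    if (!is.matrix(s) || ncol(s) != 2L)
        stop("a spectrum must be a two-column (mz, intensity) matrix")
    storage.mode(s) <- "double"
    s <- s[order(s[, 1L]), , drop = FALSE]
    dimnames(s) <- list(NULL, c("mz", "intensity"))
    s
}

#' Reset feature attributions to unrated
#'
#' Clears TRF / SRF / fragment attributions (and the associated adduct labels
#' and group ids) so that a table can be re-rated, e.g. after subsetting to
#' the final feature set. Interference marks from the prefilters are kept
#' unless `keepInterference = FALSE`.
#'
#' @param x A [PeakTable].
#' @param keepInterference logical; keep `interference` marks (default).
#' @return The modified [PeakTable].
#' @export
resetAttributions <- function(x, keepInterference = TRUE) {
    at <- rowData(x)$attribution
    keep <- if (keepInterference) at == "interference" else rep(FALSE, length(at))
    rowData(x)$attribution[!keep] <- "unrated"
    rowData(x)$adduct_label[!keep] <- NA_character_
    rowData(x)$group_id[!keep] <- NA_character_
    if ("is_representative" %in% colnames(rowData(x)))
        rowData(x)$is_representative <- NULL
    validObject(x)
    x
}

# deterministic zero-padded token series, e.g. CL0001 CL0002 ...
.tokenSeries <- function(prefix, n) {
    if (n == 0L) return(character())
    sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

.roundReport <- function(x, digits) {
    ifelse(is.na(x), NA_real_, round(x, digits))
}
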