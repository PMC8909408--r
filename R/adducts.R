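#' @include AllClasses.R accessors.R
#' @importFrom stats cor
NULL

# electron-mass-corrected cation/anion offsets (Da); correctness at the
# 0.01 Da flagging scale requires the electron correction
.CATION_OFFSETS <- c("[M+H]+" = 1.007276, "[M+NH4]+" = 18.033823,
                     "[M+Na]+" = 22.989218, "[M+K]+" = 38.963158)
.ANION_OFFSETS <- c("[M-H]-" = -1.007276, "[M-H2O-H]-" = -19.018390,
                    "[M+Cl]-" = 34.969402, "[M+FA-H]-" = 44.998204)

#' Define an ionisation adduct
#'
#' An adduct is described by its canonical label, polarity, charge and signed
#' mass offset in Da (the difference between the ion m/z and the neutral
#' monoisotopic mass, electron mass included).
#'
#' @param name canonical label, e.g. `"[M+H]+"`.
#' @param massOffset signed offset in Da.
#' @param polarity `"positive"` or `"negative"`.
#' @param charge absolute charge; only singly charged species are currently
#'   supported.
#' @return A one-row `data.frame` (class `adductSpec` rows are plain rows of
#'   the spec table; combine with `rbind`).
#' @export
adductSpec <- function(name, massOffset, polarity = c("positive", "negative"),
                       charge = 1L) {
    polarity <- match.arg(polarity)
    if (charge != 1L)
        stop("only singly charged adducts are supported")
    data.frame(name = name, polarity = polarity, charge = as.integer(charge),
               mass_offset = as.numeric(massOffset))
}

#' Built-in adduct sets
#'
#' `defaultPositiveAdducts()` returns the four singly charged positive-mode
#' species `[M+H]+`, `[M+NH4]+`, `[M+Na]+`, `[M+K]+` with electron-corrected
#' monoisotopic offsets. `defaultNegativeAdducts()` is a documented example
#' set for negative mode (`[M-H]-`, `[M-H2O-H]-`, `[M+Cl]-`, `[M+FA-H]-`);
#' arbitrary user sets are supported through [adductSpec()] + [buildRules()].
#'
#' @return A `data.frame` of adduct specs.
#' @export
defaultPositiveAdducts <- function() {
    do.call(rbind, lapply(names(.CATION_OFFSETS), function(nm)
        adductSpec(nm, .CATION_OFFSETS[[nm]], "positive")))
}

#' @rdname defaultPositiveAdducts
#' @export
defaultNegativeAdducts <- function() {
    do.call(rbind, lapply(names(.ANION_OFFSETS), function(nm)
        adductSpec(nm, .ANION_OFFSETS[[nm]], "negative")))
}

#' Build adduct-correlation rules from adduct specs
#'
#' An adduct-correlation rule is the fixed m/z difference expected between
#' two adduct forms of one molecule: `delta = |offset(high) - offset(low)|`,
#' with the pair ordered so that `delta > 0`. Duplicate pairs collapse to
#' one rule.
#'
#' @param specs `data.frame` of adduct specs ([adductSpec()] rows).
#' @param pairs list of length-2 character vectors naming the paired specs;
#'   default: all unordered pairs.
#' @param tolerance matching tolerance in Da (default 0.01).
#' @return A `data.frame` with columns `low`, `high`, `delta`, `tolerance`,
#'   `low_offset`, `high_offset`.
#' @examples
#' rules <- buildRules(defaultPositiveAdducts())   # all 6 pairs of 4 adducts
#' @export
buildRules <- function(specs, pairs = NULL, tolerance = 0.01) {
    stopifnot(is.data.frame(specs), nrow(specs) >= 2L, tolerance > 0)
    if (anyDuplicated(specs$name))
        stop("adduct config error: duplicate adduct name")
    if (length(unique(specs$polarity)) != 1L)
        stop("adduct config error: specs mix polarities")
    if (is.null(pairs)) {
        idx <- utils::combn(nrow(specs), 2L)
        pairs <- lapply(seq_len(ncol(idx)), function(k)
            specs$name[idx[, k]])
    }
    if (!length(pairs))
        return(data.frame(low = character(), high = character(),
                          delta = numeric(), tolerance = numeric(),
                          low_offset = numeric(), high_offset = numeric()))
    rules <- lapply(pairs, function(p) {
        if (length(p) != 2L)
            stop("adduct config error: a pair must name exactly two adducts")
        i <- match(p, specs$name)
        if (anyNA(i))
            stop("adduct config error: unknown adduct name: ",
                 paste(p[is.na(i)], collapse = ", "))
        if (i[1L] == i[2L])
            stop("adduct config error: a pair must name two distinct adducts")
        off <- specs$mass_offset[i]
        if (off[1L] == off[2L])
            stop("adduct config error: degenerate rule, equal offsets for ",
                 p[1L], " and ", p[2L])
        o <- order(off)
        data.frame(low = specs$name[i][o][1L], high = specs$name[i][o][2L],
                   delta = diff(off[o]), tolerance = tolerance,
                   low_offset = off[o][1L], high_offset = off[o][2L])
    })
    out <- do.call(rbind, rules)
    out <- out[!duplicated(out[, c("low", "high")]), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' The six positive-mode correlation rules
#'
#' The default rule set used for positive-mode flagging: the six pairwise
#' correlations among `[M+H]+`, `[M+NH4]+`, `[M+Na]+` and `[M+K]+`.
#'
#' @param tolerance matching tolerance in Da (default 0.01).
#' @return A rule `data.frame`, see [buildRules()].
#' @export
defaultPositiveRules <- function(tolerance = 0.01)
    buildRules(defaultPositiveAdducts(), tolerance = tolerance)

#' Back-calculate a neutral monoisotopic mass
#'
#' @param mzValue observed ion m/z (Da).
#' @param adductName adduct label present in `specs`.
#' @param specs adduct spec table (default [defaultPositiveAdducts()]).
#' @return Neutral mass in Da.
#' @export
neutralMass <- function(mzValue, adductName, specs = defaultPositiveAdducts()) {
    i <- match(adductName, specs$name)
    if (is.na(i)) stop("unknown adduct: ", adductName)
    m <- mzValue * specs$charge[i] - specs$mass_offset[i]
    if (any(m <= 0))
        stop("non-physical neutral mass (<= 0) for m/z ", mzValue,
             " as ", adductName)
    m
}

# all candidate correlation edges in one cluster:
# pairs (i, j) with mz_j > mz_i matching a rule's delta within its tolerance
.candidateEdges <- function(ids, mzs, rules) {
    out <- data.frame(i = integer(), j = integer(), rule = integer(),
                      error = numeric())
    n <- length(ids)
    if (n < 2L || !nrow(rules)) return(out)
    cmb <- utils::combn(n, 2L)
    lo <- ifelse(mzs[cmb[1L, ]] <= mzs[cmb[2L, ]], cmb[1L, ], cmb[2L, ])
    hi <- ifelse(mzs[cmb[1L, ]] <= mzs[cmb[2L, ]], cmb[2L, ], cmb[1L, ])
    d <- mzs[hi] - mzs[lo]
    for (r in seq_len(nrow(rules))) {
        err <- abs(d - rules$delta[r])
        hit <- which(err <= rules$tolerance[r] & d > 0)
        if (length(hit))
            out <- rbind(out, data.frame(i = lo[hit], j = hi[hit],
                                         rule = r, error = err[hit]))
    }
    out
}

# exact resolution of candidate edges to one label per feature.
# maximises the number of satisfied edges; ties broken by minimal total
# absolute mass error, then by the lexicographically smallest label vector
# (features in input order, label order: unlabelled first, then rule-set
# order). Enumeration is restricted to labels occurring in candidate edges,
# which provably contains an optimum; a greedy pass (ascending error,
# compatibility-checked) is the fallback above `maxAssignments`.
.resolveLabels <- function(edges, n, rules, labelLevels,
                           maxAssignments = 2e5) {
    labels <- rep(NA_character_, n)
    if (!nrow(edges)) return(list(labels = labels, accepted = integer()))
    inv <- sort(unique(c(edges$i, edges$j)))
    allowed <- lapply(inv, function(f) {
        ls <- unique(c(rules$low[edges$rule[edges$i == f]],
                       rules$high[edges$rule[edges$j == f]]))
        c(NA_character_, ls[order(match(ls, labelLevels))])
    })
    n_assign <- prod(lengths(allowed))
    if (n_assign <= maxAssignments) {
        # full product over allowed labels, lexicographic order
        grid <- do.call(expand.grid,
                        c(rev(lapply(allowed, seq_along)),
                          list(KEEP.OUT.ATTRS = FALSE)))
        grid <- grid[, rev(seq_along(allowed)), drop = FALSE]
        lab_of <- function(col, idx) allowed[[col]][idx]
        ei <- match(edges$i, inv); ej <- match(edges$j, inv)
        low <- rules$low[edges$rule]; high <- rules$high[edges$rule]
        sat_count <- numeric(nrow(grid))
        sat_err <- numeric(nrow(grid))
        sat_mat <- matrix(FALSE, nrow(grid), nrow(edges))
        for (e in seq_len(nrow(edges))) {
            li <- lab_of(ei[e], grid[[ei[e]]])
            lj <- lab_of(ej[e], grid[[ej[e]]])
            ok <- !is.na(li) & !is.na(lj) & li == low[e] & lj == high[e]
            sat_mat[, e] <- ok
            sat_count <- sat_count + ok
            sat_err <- sat_err + ok * edges$error[e]
        }
        best <- which(sat_count == max(sat_count))
        best <- best[sat_err[best] == min(sat_err[best])]
        pick <- best[1L]   # grid rows enumerate lexicographically
        for (k in seq_along(inv))
            labels[inv[k]] <- allowed[[k]][grid[pick, k]]
        accepted <- which(sat_mat[pick, ])
    } else {
        # greedy fallback: ascending error, accept when label-compatible
        ord <- order(edges$error, edges$i, edges$j, edges$rule)
        accepted <- integer()
        for (e in ord) {
            li <- labels[edges$i[e]]; lj <- labels[edges$j[e]]
            low <- rules$low[edges$rule[e]]; high <- rules$high[edges$rule[e]]
            if ((is.na(li) || li == low) && (is.na(lj) || lj == high)) {
                labels[edges$i[e]] <- low
                labels[edges$j[e]] <- high
                accepted <- c(accepted, e)
            }
        }
        accepted <- sort(accepted)
    }
    # canonicalise: drop labels carried by no accepted edge
    carried <- unique(c(edges$i[accepted], edges$j[accepted]))
    labels[setdiff(seq_len(n), carried)] <- NA_character_
    list(labels = labels, accepted = accepted)
}

#' Flag adduct correlations within one feature cluster
#'
#' Within a cluster, every feature pair whose m/z difference matches an
#' expected adduct-correlation delta (within the rule's tolerance) is a
#' candidate edge. Candidates are resolved to at most one adduct label per
#' feature by exact maximisation of the number of accepted edges (ties:
#' minimal total absolute mass error); connected components of accepted
#' edges become TRF correlation groups. Features carrying a label are
#' top-rated features (TRFs).
#'
#' In strict mode the manual-annotation criterion is additionally imposed on
#' candidate edges: the two features must co-elute within `strictRtTol`
#' minutes and their biological height vectors must have Pearson correlation
#' at least `strictMinPearson`. Default mode trusts cluster membership
#' as-is.
#'
#' @param table A [PeakTable].
#' @param members character vector of feature ids forming one cluster.
#' @param rules rule `data.frame` from [buildRules()] /
#'   [defaultPositiveRules()].
#' @param strict impose the co-elution/correlation check on each edge?
#' @param strictRtTol,strictMinPearson strict-mode thresholds (0.03 min,
#'   0.8).
#' @return A list with `assignments` (`data.frame`: `feature_id`,
#'   `adduct_label`, `group` — a cluster-local integer), and `evidence`
#'   (`data.frame`: `feature_id`, `partner_id`, `rule`, `error_da`).
#' @examples
#' pt <- PeakTable(
#'   features = data.frame(feature_id = c("A", "B"),
#'                         mz = c(381.1161, 397.0894), rt = c(4.12, 4.11)),
#'   samples = data.frame(sample_id = "S1"))
#' flagCluster(pt, c("A", "B"), defaultPositiveRules())$assignments
#' @export
flagCluster <- function(table, members, rules, strict = FALSE,
                        strictRtTol = 0.03, strictMinPearson = 0.8) {
    empty <- list(assignments = data.frame(feature_id = character(),
                                           adduct_label = character(),
                                           group = integer()),
                  evidence = data.frame(feature_id = character(),
                                        partner_id = character(),
                                        rule = character(),
                                        error_da = numeric()))
    if (length(members) < 2L) return(empty)
    miss <- setdiff(members, featureIds(table))
    if (length(miss))
        stop("unknown feature id(s): ", paste(miss, collapse = ", "))
    # canonical member order (mz then id) makes flagging order-invariant
    mzs_all <- mz(table)[members]
    members <- members[order(mzs_all, members)]
    mzs <- mz(table)[members]
    edges <- .candidateEdges(members, mzs, rules)
    if (isTRUE(strict) && nrow(edges)) {
        rts <- rt(table)[members]
        bio <- biologicalSamples(table)
        h <- heights(table)[members, bio, drop = FALSE]
        ok <- vapply(seq_len(nrow(edges)), function(e) {
            i <- edges$i[e]; j <- edges$j[e]
            if (abs(rts[i] - rts[j]) > strictRtTol) return(FALSE)
            if (length(bio) < 3L) return(FALSE)
            if (sd(h[i, ]) == 0 || sd(h[j, ]) == 0) return(FALSE)
            cor(h[i, ], h[j, ]) >= strictMinPearson
        }, logical(1L))
        edges <- edges[ok, , drop = FALSE]
    }
    if (!nrow(edges)) return(empty)
    labelLevels <- unique(c(rules$low, rules$high))
    res <- .resolveLabels(edges, length(members), rules, labelLevels)
    acc <- edges[res$accepted, , drop = FALSE]
    if (!nrow(acc)) return(empty)
    # groups: connected components of accepted edges, ordered by min member mz
    g <- igraph::graph_from_data_frame(
        data.frame(from = members[acc$i], to = members[acc$j]),
        directed = FALSE, vertices = members)
    comp <- igraph::components(g)$membership[members]
    flagged <- sort(unique(c(acc$i, acc$j)))
    comp_min_mz <- tapply(mzs[flagged], comp[flagged], min)
    grp_rank <- rank(comp_min_mz, ties.method = "first")
    assignments <- data.frame(
        feature_id = members[flagged],
        adduct_label = res$labels[flagged],
        group = as.integer(grp_rank[as.character(comp[flagged])]))
    rule_name <- sprintf("%s->%s", rules$low[acc$rule], rules$high[acc$rule])
    evidence <- rbind(
        data.frame(feature_id = members[acc$i], partner_id = members[acc$j],
                   rule = rule_name, error_da = acc$error),
        data.frame(feature_id = members[acc$j], partner_id = members[acc$i],
                   rule = rule_name, error_da = acc$error))
    evidence <- evidence[order(evidence$feature_id, evidence$partner_id), ]
    rownames(evidence) <- NULL
    list(assignments = assignments, evidence = evidence)
}
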