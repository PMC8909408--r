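# Fixture builders and independent brute-force oracles used across the suite.

# Minimal PeakTable builder: features as a data.frame, heights filled with
# distinct constants unless given, spectra optional.
makeTable <- function(features, heights = NULL, samples = NULL,
                      spectra = NULL, polarity = "positive") {
    n <- nrow(features)
    if (is.null(samples))
        samples <- data.frame(sample_id = c("S1", "S2", "S3"),
                              role = "biological",
                              class_label = c("c1", "c1", "c2"))
    if (is.null(heights))
        heights <- matrix(rep(100 * seq_len(n), nrow(samples)),
                          nrow = n, ncol = nrow(samples),
                          dimnames = list(NULL, samples$sample_id))
    PeakTable(features = features, heights = heights, samples = samples,
              spectra = spectra, polarity = polarity)
}

# --- independent exhaustive oracle for adduct-label resolution -------------
# Full product over the whole label alphabet (every adduct name + none) for
# every feature; maximises the satisfied-edge count, ties by minimal total
# absolute error, then by the lexicographically smallest label vector
# (features in mz order, labels ordered none-first then rule-set order).
# Deliberately dumb; only feasible for small clusters.
oracleFlag <- function(mzs, ids, rules) {
    o <- order(mzs, ids)
    ids <- ids[o]; mzs <- mzs[o]
    n <- length(ids)
    alphabet <- c(NA_character_, unique(c(rules$low, rules$high)))
    # candidate edges by definition
    edges <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (mzs[j] <= mzs[i]) next
        for (r in seq_len(nrow(rules))) {
            err <- abs((mzs[j] - mzs[i]) - rules$delta[r])
            if (err <= rules$tolerance[r])
                edges[[length(edges) + 1L]] <-
                    list(i = i, j = j, low = rules$low[r],
                         high = rules$high[r], err = err)
        }
    }
    # every assignment of the full alphabet to every feature, rows in
    # lexicographic order (first feature most significant)
    grid <- expand.grid(rev(rep(list(seq_along(alphabet)), n)),
                        KEEP.OUT.ATTRS = FALSE)[, rev(seq_len(n)),
                                                drop = FALSE]
    sat <- numeric(nrow(grid)); err <- numeric(nrow(grid))
    sat_by_edge <- matrix(FALSE, nrow(grid), length(edges))
    for (ei in seq_along(edges)) {
        e <- edges[[ei]]
        li <- alphabet[grid[[e$i]]]; lj <- alphabet[grid[[e$j]]]
        ok <- !is.na(li) & !is.na(lj) & li == e$low & lj == e$high
        sat_by_edge[, ei] <- ok
        sat <- sat + ok
        err <- err + ok * e$err
    }
    opt <- which(sat == max(sat))
    opt <- opt[err[opt] <= min(err[opt]) + 1e-12]
    pick <- opt[1L]   # first in lexicographic order
    labs <- alphabet[as.integer(grid[pick, ])]
    # canonicalise: drop labels with no satisfied incident edge
    carried <- rep(FALSE, n)
    for (e in edges)
        if (!is.na(labs[e$i]) && !is.na(labs[e$j]) &&
            labs[e$i] == e$low && labs[e$j] == e$high)
            carried[c(e$i, e$j)] <- TRUE
    labs[!carried] <- NA_character_
    stats::setNames(labs, ids)
}

# --- independent triple-loop oracle for fragment screening -----------------
oracleFragments <- function(mzs, ids, spectra, trf_ids, tol) {
    calls <- character()
    for (f in seq_along(ids)) {
        if (ids[f] %in% trf_ids) next
        hit <- FALSE
        for (g in seq_along(ids)) {
            if (g == f || mzs[g] <= mzs[f]) next
            s <- spectra[[g]]
            if (is.null(s) || nrow(s) == 0L) next
            for (p in seq_len(nrow(s)))
                if (abs(mzs[f] - s[p, 1L]) <= tol) hit <- TRUE
        }
        if (hit) calls <- c(calls, ids[f])
    }
    calls
}

# random cluster with planted adduct relations plus unrelated features;
# returns a PeakTable whose features form one cluster
randomAdductCluster <- function(n_max = 6L, rules = defaultPositiveRules(),
                                specs = defaultPositiveAdducts()) {
    n <- sample(2:n_max, 1L)
    n_planted <- sample(0:min(n, nrow(specs)), 1L)
    mzs <- numeric()
    if (n_planted > 0L) {
        M <- runif(1, 150, 900)
        which_add <- sample(nrow(specs), n_planted)
        mzs <- M + specs$mass_offset[which_add] + rnorm(n_planted, 0, 0.002)
    }
    while (length(mzs) < n) {
        cand <- runif(1, 100, 1000)
        mzs <- c(mzs, cand)
    }
    ids <- sprintf("X%02d", seq_len(n))
    makeTable(data.frame(feature_id = ids, mz = mzs, rt = 5,
                         cluster_id = "CL1"))
}

# random cluster with spectra for the fragment-screen oracle
randomFragmentCluster <- function(n_max = 8L, max_peaks = 20L) {
    n <- sample(2:n_max, 1L)
    mzs <- sort(runif(n, 100, 900))
    ids <- sprintf("X%02d", seq_len(n))
    spectra <- lapply(seq_len(n), function(i) {
        np <- sample(0:max_peaks, 1L)
        if (np == 0L) return(NULL)
        # some peaks deliberately near other members' MS1 m/z
        p <- runif(np, 50, mzs[i])
        near <- runif(np) < 0.3
        if (any(near))
            p[near] <- sample(mzs, sum(near), replace = TRUE) +
                runif(sum(near), -0.08, 0.08)
        cbind(p, runif(np, 1, 1000))
    })
    trf <- ids[runif(n) < 0.2]
    list(table = makeTable(data.frame(feature_id = ids, mz = mzs, rt = 3,
                                      cluster_id = "CL1"),
                           spectra = spectra),
         ids = ids, mzs = mzs, spectra = lapply(spectra, peakRating:::.asSpectrum),
         trf = trf)
}
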