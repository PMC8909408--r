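#' @include AllClasses.R adducts.R
#' @importFrom stats rnorm runif rlnorm setNames
NULL

# small table of chemically plausible neutral losses (Da): water, formic
# acid, hexose; uniform deviates are mixed in so fragment matching is
# exercised across magnitudes
.NEUTRAL_LOSSES <- c(18.010565, 46.005480, 162.052824)

#' Simulation configuration for synthetic peak tables
#'
#' Describes a synthetic untargeted LC-MS study with known ground truth:
#' `nCompounds` molecules, each emitting a quasi-molecular ion (unless
#' dropped with probability `pDropQuasimolecular`, in which case at least
#' two other adducts are forced so the compound stays discoverable through
#' adduct correlations), optional extra adducts at exact offsets plus
#' Gaussian m/z jitter, and with probability `pFragment` one or more
#' in-source fragments whose m/z is planted in the precursor feature's MS2
#' spectrum. Per-compound latent abundances vary by biological class and
#' sample and are shared by all features of the compound, making
#' within-compound features Pearson-correlated while keeping within-class
#' RSD modest; blanks carry near-zero heights for compound features; QC
#' samples are per-feature means of the biological samples plus small
#' noise. Uncorrelated noise singletons are added, a configurable fraction
#' of them blank-dominated (to exercise the blank filter).
#'
#' @param nCompounds number of molecules.
#' @param neutralMassRange Da interval for neutral monoisotopic masses.
#' @param adducts adduct spec table; the first row is the quasi-molecular
#'   base form.
#' @param pExtraAdduct inclusion probability of each non-base adduct.
#' @param pDropQuasimolecular probability that the base form is absent.
#' @param pFragment probability that a compound sheds in-source fragments.
#' @param fragmentsPerParent integer range (min, max) of fragments per
#'   shedding compound.
#' @param nClasses,replicatesPerClass biological design (default 4 x 3).
#' @param nBlanks,nQc blank and pooled-QC sample counts.
#' @param intensityCv coefficient of variation of the multiplicative
#'   per-feature intensity noise.
#' @param mzJitterSd,rtJitterSd Gaussian jitter (Da / minutes) on feature
#'   m/z and RT.
#' @param nNoiseFeatures number of uncorrelated singleton noise features.
#' @param blankNoiseFraction fraction of noise features dominated by the
#'   blank.
#' @param seed integer seed; mandatory, the generator is fully
#'   deterministic given the config.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(nCompounds = 200, neutralMassRange = c(150, 1000),
                      adducts = defaultPositiveAdducts(),
                      pExtraAdduct = 0.4, pDropQuasimolecular = 0.1,
                      pFragment = 0.3, fragmentsPerParent = c(1L, 2L),
                      nClasses = 4L, replicatesPerClass = 3L,
                      nBlanks = 1L, nQc = 2L, intensityCv = 0.2,
                      mzJitterSd = 0.002, rtJitterSd = 0.005,
                      nNoiseFeatures = 50L, blankNoiseFraction = 0.3,
                      seed) {
    if (missing(seed)) stop("simConfig: seed is mandatory")
    stopifnot(nCompounds >= 0, length(neutralMassRange) == 2L,
              diff(neutralMassRange) >= 0,
              pExtraAdduct >= 0, pExtraAdduct <= 1,
              pDropQuasimolecular >= 0, pDropQuasimolecular <= 1,
              pFragment >= 0, pFragment <= 1,
              length(fragmentsPerParent) == 2L,
              fragmentsPerParent[1L] >= 1L,
              fragmentsPerParent[2L] >= fragmentsPerParent[1L],
              nClasses >= 1L, replicatesPerClass >= 1L,
              nBlanks >= 0, nQc >= 0, intensityCv > 0,
              mzJitterSd >= 0, rtJitterSd >= 0,
              nNoiseFeatures >= 0,
              blankNoiseFraction >= 0, blankNoiseFraction <= 1)
    if (pDropQuasimolecular > 0 && nrow(adducts) < 3L)
        stop("infeasible config: dropping the quasi-molecular ion needs at ",
             "least two alternative adducts in the set")
    structure(as.list(environment()), class = "simConfig")
}

# draw a fragment m/z below `precursor` that neither collides with an
# adduct-correlation delta against any existing cluster member nor sits on
# top of one
.drawFragmentMz <- function(precursor, existing_mz, rules, guard = 0.05) {
    for (try in seq_len(100L)) {
        loss <- if (runif(1) < 0.6)
            .NEUTRAL_LOSSES[sample.int(length(.NEUTRAL_LOSSES), 1L)]
        else runif(1, 20, 120)
        fmz <- precursor - loss
        if (fmz <= 60) next
        deltas <- abs(existing_mz - fmz)
        if (any(deltas < 0.2)) next
        clash <- any(vapply(rules$delta, function(d)
            any(abs(deltas - d) <= guard), logical(1L)))
        if (!clash) return(fmz)
    }
    stop("could not place a fragment without an adduct-delta collision")
}

#' Generate a synthetic peak table with known ground truth
#'
#' @param cfg A [simConfig()].
#' @return A list with `table` (a [PeakTable], features ordered by RT then
#'   m/z, cluster ids pre-assigned per compound) and `truth` (a list:
#'   `roles` — named `parental`/`adduct`/`fragment`/`noise`;
#'   `compound_of` — compound token per non-noise feature;
#'   `adduct_of` — planted adduct name per parental/adduct feature;
#'   `expected_attribution` — what the feature-rating rule should return
#'   per feature given the planted construction: TRF for members of
#'   compounds with two or more correlated adduct forms, fragment for
#'   planted fragments, interference for blank-dominated noise once the
#'   blank filter has run, SRF otherwise;
#'   `expected_clusters` — the per-compound partition of feature ids).
#' @examples
#' sim <- simulatePeakTable(simConfig(nCompounds = 5, nNoiseFeatures = 2,
#'                                    seed = 1))
#' sim$table
#' table(sim$truth$roles)
#' @export
simulatePeakTable <- function(cfg) {
    stopifnot(inherits(cfg, "simConfig"))
    set.seed(cfg$seed)
    adducts <- cfg$adducts
    rules <- buildRules(adducts, tolerance = 0.01)
    polarity <- adducts$polarity[1L]

    classes <- sprintf("class%02d", seq_len(cfg$nClasses))
    bio_ids <- as.vector(vapply(classes, function(cl)
        sprintf("%s_r%d", cl, seq_len(cfg$replicatesPerClass)),
        character(cfg$replicatesPerClass)))
    blank_ids <- if (cfg$nBlanks) sprintf("blank_%d", seq_len(cfg$nBlanks))
        else character()
    qc_ids <- if (cfg$nQc) sprintf("QC_%d", seq_len(cfg$nQc)) else character()
    samples <- data.frame(
        sample_id = c(bio_ids, blank_ids, qc_ids),
        role = c(rep("biological", length(bio_ids)),
                 rep("blank", length(blank_ids)),
                 rep("qc", length(qc_ids))),
        class_label = c(rep(classes, each = cfg$replicatesPerClass),
                        rep("blank", length(blank_ids)),
                        rep("QC", length(qc_ids))))
    nb <- length(bio_ids)
    sdlog <- sqrt(log(1 + cfg$intensityCv^2))

    rows <- list(); hts <- list(); sp <- list()
    roles <- character(); compound_of <- character()
    adduct_of <- character(); expected <- character()
    blank_dominated <- logical()
    clusters <- list()
    k <- 0L
    addRow <- function(mzv, rtv, bio_h, role, comp, add_label, exp_attr,
                       blank_dom = FALSE) {
        k <<- k + 1L
        rows[[k]] <<- c(mzv, rtv)
        hts[[k]] <<- bio_h
        sp[k] <<- list(NULL)
        roles[k] <<- role
        compound_of[k] <<- comp
        adduct_of[k] <<- add_label
        expected[k] <<- exp_attr
        blank_dominated[k] <<- blank_dom
        k
    }

    for (ci in seq_len(cfg$nCompounds)) {
        comp <- sprintf("CMP%04d", ci)
        M <- runif(1, cfg$neutralMassRange[1L], cfg$neutralMassRange[2L])
        RT <- runif(1, 1, 18)
        # latent abundance shared by all features of the compound:
        # class effect (between-class contrast) x small shared per-sample
        # effect; the per-feature lognormal noise (cv = intensityCv) comes
        # on top, so within-compound features stay Pearson-correlated while
        # within-class RSD stays below the filter default
        base_abund <- rlnorm(1, log(1e5), 0.5)
        class_eff <- rlnorm(cfg$nClasses, 0, 0.8)
        sample_eff <- rlnorm(nb, 0, 0.15)
        latent <- base_abund * rep(class_eff, each = cfg$replicatesPerClass) *
            sample_eff

        present <- rep(FALSE, nrow(adducts))
        present[1L] <- runif(1) >= cfg$pDropQuasimolecular
        if (nrow(adducts) > 1L)
            present[-1L] <- runif(nrow(adducts) - 1L) < cfg$pExtraAdduct
        if (!present[1L] && sum(present) < 2L) {
            off <- setdiff(which(!present), 1L)
            force_n <- 2L - sum(present)
            present[off[sample.int(length(off), force_n)]] <- TRUE
        }
        idx <- which(present)
        members <- integer()
        mzs_here <- numeric()
        for (ai in idx) {
            resp <- rlnorm(1, 0, 0.5)
            bh <- latent * resp * rlnorm(nb, 0, sdlog)
            mzv <- M + adducts$mass_offset[ai] + rnorm(1, 0, cfg$mzJitterSd)
            members <- c(members, addRow(
                mzv, RT + rnorm(1, 0, cfg$rtJitterSd), bh,
                role = if (ai == 1L) "parental" else "adduct",
                comp = comp, add_label = adducts$name[ai],
                exp_attr = if (length(idx) >= 2L) "TRF" else "SRF"))
            mzs_here <- c(mzs_here, mzv)
        }
        precursor_k <- members[1L]
        planted_spec <- NULL
        if (runif(1) < cfg$pFragment) {
            span <- cfg$fragmentsPerParent[2L] - cfg$fragmentsPerParent[1L] + 1L
            nf <- cfg$fragmentsPerParent[1L] + sample.int(span, 1L) - 1L
            for (f in seq_len(nf)) {
                fmz0 <- .drawFragmentMz(mzs_here[1L], mzs_here, rules)
                fmz <- fmz0 + rnorm(1, 0, cfg$mzJitterSd)
                resp <- rlnorm(1, 0, 0.5)
                bh <- latent * resp * rlnorm(nb, 0, sdlog)
                members <- c(members, addRow(
                    fmz, RT + rnorm(1, 0, cfg$rtJitterSd), bh,
                    role = "fragment", comp = comp,
                    add_label = NA_character_, exp_attr = "fragment"))
                mzs_here <- c(mzs_here, fmz)
                # plant the fragment's m/z in the precursor MS2
                planted_spec <- rbind(planted_spec,
                                      c(fmz + rnorm(1, 0, cfg$mzJitterSd),
                                        runif(1, 100, 1000)))
            }
        }
        # background MS2 peaks for the precursor, kept clear of every
        # member's MS1 m/z so no spurious fragment call can arise
        bg_n <- sample.int(6L, 1L) + 2L
        bg <- cbind(runif(bg_n, 60, max(mzs_here[1L], 61)),
                    runif(bg_n, 10, 500))
        bg <- bg[vapply(bg[, 1L], function(p)
            all(abs(p - mzs_here) > 0.2), logical(1L)), , drop = FALSE]
        sp[[precursor_k]] <- rbind(planted_spec, bg)
        clusters[[comp]] <- members
    }

    # noise: uncorrelated singletons with a stable per-class pattern, a
    # configurable fraction dominated by the blank
    n_blank_noise <- round(cfg$nNoiseFeatures * cfg$blankNoiseFraction)
    for (ni in seq_len(cfg$nNoiseFeatures)) {
        blank_dom <- ni <= n_blank_noise
        scale <- if (blank_dom) 200 else 2e4
        bh <- scale * rep(rlnorm(cfg$nClasses, 0, 1.2),
                          each = cfg$replicatesPerClass) *
            rlnorm(nb, 0, sdlog)
        ki <- addRow(runif(1, 100, 1200), runif(1, 1, 18), bh,
                     role = "noise", comp = NA_character_,
                     add_label = NA_character_,
                     exp_attr = if (blank_dom && cfg$nBlanks > 0)
                         "interference" else "SRF",
                     blank_dom = blank_dom)
        clusters[[sprintf("NOISE%04d", ni)]] <- ki
    }

    n <- k
    if (n == 0L) {
        pt <- PeakTable(features = data.frame(feature_id = character(),
                                              mz = numeric(), rt = numeric()),
                        samples = samples, polarity = polarity,
                        provenance = "simulated empty table")
        return(list(table = pt,
                    truth = list(roles = character(),
                                 compound_of = character(),
                                 adduct_of = character(),
                                 expected_attribution = character(),
                                 expected_clusters = list())))
    }
    mz_all <- vapply(rows, `[`, 0, 1L)
    rt_all <- vapply(rows, `[`, 0, 2L)
    H <- do.call(rbind, hts)                       # biological heights
    blank_h <- matrix(runif(n * cfg$nBlanks, 0, 50), nrow = n,
                      ncol = cfg$nBlanks)
    if (cfg$nBlanks > 0 && any(blank_dominated))
        blank_h[blank_dominated, ] <-
            matrix(rlnorm(sum(blank_dominated) * cfg$nBlanks, log(5e4), 0.3),
                   ncol = cfg$nBlanks)
    qc_h <- if (cfg$nQc > 0)
        rowMeans(H) * matrix(rlnorm(n * cfg$nQc, 0, sdlog / 2), nrow = n)
    else matrix(numeric(), nrow = n, ncol = 0L)
    heights <- cbind(H, blank_h, qc_h)
    colnames(heights) <- samples$sample_id

    # order features chromatographically; assign ids afterwards
    ord <- order(rt_all, mz_all)
    fid <- .tokenSeries("F", n)
    old2new <- character(n)
    old2new[ord] <- fid
    cluster_members <- lapply(clusters, function(ix) unname(old2new[ix]))
    # cluster ids ordered by lowest member m/z (same convention as
    # clusterFeatures)
    cl_min <- vapply(clusters, function(ix) min(mz_all[ix]), 0)
    cl_rank <- rank(cl_min, ties.method = "first")
    cl_ids <- .tokenSeries("CL", length(clusters))[cl_rank]
    cluster_of <- character(n)
    for (ci in seq_along(clusters)) cluster_of[clusters[[ci]]] <- cl_ids[ci]

    features <- data.frame(feature_id = fid,
                           mz = mz_all[ord], rt = rt_all[ord],
                           cluster_id = cluster_of[ord],
                           upstream_adduct = NA_character_)
    spectra <- lapply(sp[ord], .asSpectrum)
    pt <- PeakTable(features = features,
                    heights = heights[ord, , drop = FALSE],
                    samples = samples, spectra = spectra, polarity = polarity,
                    provenance = sprintf(
                        "simulated %d features (%d compounds, %d noise), seed %d",
                        n, cfg$nCompounds, cfg$nNoiseFeatures, cfg$seed))
    nm <- function(v) { x <- v[ord]; names(x) <- fid; x }
    truth <- list(roles = nm(roles),
                  compound_of = nm(compound_of),
                  adduct_of = nm(adduct_of),
                  expected_attribution = nm(expected),
                  expected_clusters = setNames(cluster_members, cl_ids))
    list(table = pt, truth = truth)
}
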