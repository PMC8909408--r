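test_that("default positive rules are the six cation pair deltas", {
    rules <- defaultPositiveRules()
    expect_equal(nrow(rules), 6L)
    key <- function(lo, hi) which(rules$low == lo & rules$high == hi)
    expect_equal(rules$delta[key("[M+Na]+", "[M+K]+")], 15.9739,
                 tolerance = 1e-4)
    expect_equal(rules$delta[key("[M+H]+", "[M+NH4]+")], 17.0265,
                 tolerance = 1e-4)
    expect_equal(rules$delta[key("[M+H]+", "[M+Na]+")], 21.981942,
                 tolerance = 1e-4)
    expect_true(all(rules$delta > 0))
    expect_true(all(rules$tolerance == 0.01))
})

test_that("buildRules supports user sets, collapses duplicates, rejects junk", {
    specs <- rbind(defaultPositiveAdducts(),
                   adductSpec("[M+H-H2O]+", 1.007276 - 18.010565, "positive"),
                   adductSpec("[M+CH3OH+H]+", 33.033489, "positive"),
                   adductSpec("[M+ACN+H]+", 42.033823, "positive"))
    # 7 adduct types -> all 21 unordered pairs
    rules <- buildRules(specs)
    expect_equal(nrow(rules), 21L)
    expect_true(all(rules$delta > 0))

    expect_equal(nrow(buildRules(specs, pairs = list())), 0L)
    expect_error(buildRules(specs, pairs = list(c("[M+H]+", "[M+H]+"))),
                 "distinct")
    expect_error(buildRules(specs, pairs = list(c("[M+H]+", "[M+X]+"))),
                 "unknown")
    # duplicate pairs collapse (order within the pair irrelevant)
    r2 <- buildRules(specs, pairs = list(c("[M+H]+", "[M+Na]+"),
                                         c("[M+Na]+", "[M+H]+")))
    expect_equal(nrow(r2), 1L)
    # equal offsets form a degenerate rule
    dg <- rbind(adductSpec("X", 5, "positive"), adductSpec("Y", 5, "positive"))
    expect_error(buildRules(dg), "degenerate")
})

test_that("neutral mass inverts the adduct construction", {
    expect_equal(neutralMass(322.9892, "[M+Na]+"), 300.0000, tolerance = 1e-4)
    expect_equal(neutralMass(301.0073, "[M+H]+"), 300.0000, tolerance = 1e-4)
    expect_error(neutralMass(10.0, "[M+Na]+"), "non-physical")
    expect_error(neutralMass(100.0, "[M+X]+"), "unknown")
})

test_that("worked adduct-pair examples flag as Na/K", {
    rules <- defaultPositiveRules()
    # sodium/potassium pair at RT ~4.1: delta 15.9733
    pt <- makeTable(data.frame(feature_id = c("A", "B"),
                               mz = c(381.1161, 397.0894),
                               rt = c(4.12, 4.11), cluster_id = "CL1"))
    fl <- flagCluster(pt, c("A", "B"), rules)
    expect_equal(fl$assignments$adduct_label[fl$assignments$feature_id == "A"],
                 "[M+Na]+")
    expect_equal(fl$assignments$adduct_label[fl$assignments$feature_id == "B"],
                 "[M+K]+")
    expect_equal(length(unique(fl$assignments$group)), 1L)

    # co-clustered but unrelated pair whose delta also matches Na->K:
    # the flagger must still flag it (cluster membership is trusted)
    pt2 <- makeTable(data.frame(feature_id = c("A", "B"),
                                mz = c(420.0889, 436.0651),
                                rt = c(4.30, 4.24), cluster_id = "CL1"))
    fl2 <- flagCluster(pt2, c("A", "B"), rules)
    expect_equal(sort(fl2$assignments$adduct_label),
                 c("[M+K]+", "[M+Na]+"))
})

test_that("strict mode re-imposes co-elution and correlation on edges", {
    samples <- data.frame(sample_id = sprintf("S%d", 1:4),
                          role = "biological", class_label = "c")
    h <- rbind(A = c(10, 20, 30, 40), B = c(40, 31, 18, 12))
    colnames(h) <- samples$sample_id
    pt <- PeakTable(data.frame(feature_id = c("A", "B"),
                               mz = c(420.0889, 436.0651),
                               rt = c(4.30, 4.24), cluster_id = "CL1"),
                    heights = h, samples = samples)
    # default mode flags; strict mode rejects (dRT 0.06 > 0.03 and r < 0.8)
    expect_equal(nrow(flagCluster(pt, c("A", "B"),
                                  defaultPositiveRules())$assignments), 2L)
    expect_equal(nrow(flagCluster(pt, c("A", "B"), defaultPositiveRules(),
                                  strict = TRUE)$assignments), 0L)
})

test_that("a full adduct series resolves into one consistent group", {
    rules <- defaultPositiveRules()
    M <- 300.0
    pt <- makeTable(data.frame(
        feature_id = c("H", "NH4", "Na"),
        mz = M + c(1.007276, 18.033823, 22.989218),
        rt = 5, cluster_id = "CL1"))
    fl <- flagCluster(pt, c("H", "NH4", "Na"), rules)
    expect_equal(nrow(fl$assignments), 3L)
    expect_equal(length(unique(fl$assignments$group)), 1L)
    lab <- setNames(fl$assignments$adduct_label, fl$assignments$feature_id)
    expect_equal(unname(lab[c("H", "NH4", "Na")]),
                 c("[M+H]+", "[M+NH4]+", "[M+Na]+"))
    # three accepted edges (all pairs), reported both ways in evidence
    expect_equal(nrow(fl$evidence), 6L)
    # group consistency: implied neutral masses agree
    nmass <- mapply(neutralMass, mz(pt)[names(lab)], lab)
    expect_lt(max(nmass) - min(nmass), 0.01 * length(lab))

    # singleton cluster: no assignments
    expect_equal(nrow(flagCluster(pt, "H", rules)$assignments), 0L)
})

test_that("flagging is invariant under member order and monotone in tolerance", {
    set.seed(101)
    for (i in 1:25) {
        pt <- randomAdductCluster()
        ids <- featureIds(pt)
        fl1 <- flagCluster(pt, ids, defaultPositiveRules())
        fl2 <- flagCluster(pt, rev(ids), defaultPositiveRules())
        expect_identical(fl1$assignments, fl2$assignments)

        wide <- flagCluster(pt, ids, defaultPositiveRules(tolerance = 0.03))
        expect_gte(nrow(wide$assignments), nrow(fl1$assignments))
    }
})

test_that("resolved labelling matches the exhaustive oracle on random clusters", {
    set.seed(202)
    rules <- defaultPositiveRules()
    for (i in 1:60) {
        pt <- randomAdductCluster()
        ids <- featureIds(pt)
        fl <- flagCluster(pt, ids, rules)
        got <- setNames(rep(NA_character_, length(ids)), ids)
        got[fl$assignments$feature_id] <- fl$assignments$adduct_label
        want <- oracleFlag(unname(mz(pt)), ids, rules)
        expect_identical(got[names(want)], want)
    }
})

test_that("flagging recovers planted adduct series exactly at zero jitter", {
    sim <- simulatePeakTable(simConfig(nCompounds = 40, mzJitterSd = 0,
                                       nNoiseFeatures = 10, seed = 77))
    res <- rateTable(sim$table)
    at <- attributions(res)
    exp_at <- sim$truth$expected_attribution
    expect_identical(sort(names(at)[at == "TRF"]),
                     sort(names(exp_at)[exp_at == "TRF"]))
    # planted adduct names recovered feature-by-feature
    asg <- adductAssignments(res)
    planted <- sim$truth$adduct_of[asg$feature_id]
    expect_identical(unname(planted), asg$adduct_label)
})
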