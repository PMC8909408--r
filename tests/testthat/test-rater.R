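# A hand-built co-eluting cluster in the spirit of the three-compound,
# twelve-feature example: three molecules with multiple adduct forms plus
# two in-source fragments planted in their precursors' MS2.
threeCompoundCluster <- function() {
    offs <- c("[M+H]+" = 1.007276, "[M+NH4]+" = 18.033823,
              "[M+Na]+" = 22.989218, "[M+K]+" = 38.963158)
    m1 <- 512.2050; m2 <- 676.2515; m3 <- 343.1180
    feats <- data.frame(
        feature_id = c("c1H", "c1NH4", "c1Na", "c1K",
                       "c2NH4", "c2Na", "c2K",
                       "c3H", "c3Na", "c3K",
                       "fragA", "fragB"),
        mz = c(m1 + offs, m2 + offs[2:4], m3 + offs[c(1, 3, 4)],
               m1 - 162.0528, m3 - 18.0106),
        rt = 7.41, cluster_id = "CL1")
    spectra <- vector("list", 12L)
    spectra[[1L]] <- cbind(m1 - 162.0528, 400)   # c1H carries fragA
    spectra[[8L]] <- cbind(m3 - 18.0106, 250)    # c3H carries fragB
    n <- nrow(feats)
    h <- matrix(rep(c(9, 8, 7, 6, 12, 11, 10, 22, 21, 20, 3, 2) * 1e4, 3),
                nrow = n,
                dimnames = list(NULL, c("S1", "S2", "S3")))
    makeTable(feats, heights = h, spectra = spectra)
}

test_that("a mixed cluster rates into 10 TRFs, 2 fragments, 0 SRFs, 3 groups", {
    pt <- threeCompoundCluster()
    res <- rateTable(pt)
    at <- attributions(res)
    expect_equal(sum(at == "TRF"), 10L)
    expect_equal(sum(at == "fragment"), 2L)
    expect_equal(sum(at == "SRF"), 0L)
    expect_equal(length(trfGroups(res)), 3L)
    expect_equal(sort(unname(at[c("fragA", "fragB")])),
                 c("fragment", "fragment"))
    # each group holds exactly one compound's adducts
    grp_of <- setNames(rep(names(trfGroups(res)),
                           lengths(trfGroups(res))),
                       unlist(trfGroups(res)))
    expect_equal(length(unique(grp_of[c("c1H", "c1NH4", "c1Na", "c1K")])), 1L)
    expect_equal(length(unique(grp_of[c("c2NH4", "c2Na", "c2K")])), 1L)
    # most intense member per group selected
    expect_setequal(unname(representatives(res)), c("c1H", "c2NH4", "c3H"))
    # final table = representatives (no SRFs here)
    expect_setequal(finalIds(res), unname(representatives(res)))
})

test_that("singleton clusters with no adducts or MS2 all become SRFs", {
    pt <- makeTable(data.frame(feature_id = c("A", "B", "C"),
                               mz = c(111.1, 222.2, 333.3),
                               rt = c(1, 2, 3),
                               cluster_id = c("CL1", "CL2", "CL3")))
    res <- rateTable(pt)
    expect_true(all(attributions(res) == "SRF"))
    expect_equal(finalIds(res), c("A", "B", "C"))   # RT order
})

test_that("rate_table refuses unclustered input", {
    pt <- makeTable(data.frame(feature_id = "A", mz = 100.1, rt = 1))
    expect_error(rateTable(pt), "clusterFeatures")
})

test_that("representative selection maximises intensity with stable ties", {
    samples <- data.frame(sample_id = c("S1", "S2", "BL"),
                          role = c("biological", "biological", "blank"),
                          class_label = c("c", "c", "blank"))
    h <- rbind(A = c(1e5, 1e5, 0), B = c(5e4, 5e4, 0), C = c(2e4, 2e4, 0))
    colnames(h) <- samples$sample_id
    pt <- PeakTable(data.frame(feature_id = c("A", "B", "C"),
                               mz = c(301.0073, 322.9892, 338.9),
                               rt = 5),
                    heights = h, samples = samples)
    expect_equal(selectRepresentative(c("A", "B", "C"), pt), "A")
    # equal means: tie broken by lower m/z
    h2 <- h; h2["B", ] <- h2["A", ]
    pt2 <- PeakTable(data.frame(feature_id = c("A", "B", "C"),
                                mz = c(322.9892, 301.0073, 338.9),
                                rt = 5),
                     heights = h2, samples = samples)
    expect_equal(selectRepresentative(c("A", "B"), pt2), "B")
    expect_equal(selectRepresentative("C", pt2), "C")
    # blank heights never enter the default metric
    h3 <- h; h3["C", "BL"] <- 1e9
    pt3 <- PeakTable(data.frame(feature_id = c("A", "B", "C"),
                                mz = c(301.0073, 322.9892, 338.9), rt = 5),
                     heights = h3, samples = samples)
    expect_equal(selectRepresentative(c("A", "C"), pt3), "A")
})

test_that("attribution summary arithmetic", {
    pt <- makeTable(data.frame(
        feature_id = c("t1", "t2", "s1", "s2", "s3", "f1"),
        mz = c(301.0073, 322.9892, 150.1, 160.2, 170.3, 280.0),
        rt = c(5, 5, 1, 2, 3, 5),
        cluster_id = c("CL1", "CL1", "CL2", "CL3", "CL4", "CL1")),
        spectra = list(cbind(280.0, 10), NULL, NULL, NULL, NULL, NULL))
    res <- rateTable(pt)
    smry <- summarizeAttributions(res)
    expect_equal(smry$counts$TRF, 2L)
    expect_equal(smry$counts$SRF, 3L)
    expect_equal(smry$counts$fragment, 1L)
    expect_equal(smry$real_fraction, 5 / 6)
    expect_equal(smry$final_table_size, 4L)   # 1 representative + 3 SRFs

    empty <- rateTable(makeTable(data.frame(feature_id = character(),
                                            mz = numeric(), rt = numeric())))
    es <- summarizeAttributions(empty)
    expect_true(es$empty)
    expect_equal(es$real_fraction, 0)
})

test_that("rating partitions the table and protects TRFs from fragment calls", {
    sim <- simulatePeakTable(simConfig(nCompounds = 30, nNoiseFeatures = 10,
                                       seed = 9))
    res <- rateTable(sim$table)
    at <- attributions(res)
    # partition: total over input, categories sum to input size
    expect_setequal(names(at), featureIds(sim$table))
    expect_equal(sum(at %in% c("TRF", "SRF", "fragment", "interference")),
                 nrow(sim$table))
    # TRF protection
    expect_equal(intersect(names(at)[at == "TRF"],
                           fragmentCalls(res)$fragment_id), character())
    # final set = representatives plus SRFs, RT-then-mz order, no duplicates
    expect_setequal(finalIds(res),
                    c(unname(representatives(res)), names(at)[at == "SRF"]))
    expect_false(is.unsorted(rt(sim$table)[finalIds(res)]))
})

test_that("a second rating pass on the final table removes nothing", {
    sim <- simulatePeakTable(simConfig(nCompounds = 30, nNoiseFeatures = 10,
                                       seed = 13))
    res <- rateTable(sim$table)
    fin <- sim$table[finalIds(res), ]
    fin <- resetAttributions(fin)
    res2 <- rateTable(fin)
    at2 <- attributions(res2)
    expect_true(all(at2 %in% c("TRF", "SRF")))
    expect_setequal(finalIds(res2), featureIds(fin))
})

test_that("rating is deterministic and permutation-invariant", {
    sim <- simulatePeakTable(simConfig(nCompounds = 20, nNoiseFeatures = 5,
                                       seed = 21))
    r1 <- rateTable(sim$table)
    r2 <- rateTable(sim$table)
    expect_identical(attributions(r1), attributions(r2))
    expect_identical(trfGroups(r1), trfGroups(r2))
    set.seed(31); perm <- sample(nrow(sim$table))
    r3 <- rateTable(sim$table[perm, ])
    expect_identical(attributions(r1)[names(attributions(r1))],
                     attributions(r3)[names(attributions(r1))])
    expect_identical(trfGroups(r1), trfGroups(r3))
    expect_identical(finalIds(r1), finalIds(r3))
})
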