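bioSamples3 <- data.frame(sample_id = c("S1", "S2", "S3", "BL", "QC1"),
                          role = c("biological", "biological", "biological",
                                   "blank", "qc"),
                          class_label = c("c1", "c1", "c2", "blank", "QC"))

test_that("internal-standard normalisation follows the hand arithmetic", {
    feats <- data.frame(feature_id = c("f", "IS"),
                        mz = c(300.1, 310.2), rt = c(4, 6))
    h <- matrix(c(100, 200,     # f in S1, S2
                  10, 20),      # IS in S1, S2
                nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("S1", "S2")))
    pt <- PeakTable(feats, heights = h,
                    samples = data.frame(sample_id = c("S1", "S2")))
    # IS median over biological = 15; f -> 100/10*15, 200/20*15 = 150, 150
    out <- normalizeInternalStandard(pt, "IS")
    expect_equal(nrow(out), 1L)                      # IS row removed
    expect_equal(unname(heights(out)["f", ]), c(150, 150))

    # constant IS: table unchanged except the IS row
    h2 <- h; h2[2L, ] <- c(10, 10)
    pt2 <- PeakTable(feats, heights = h2,
                     samples = data.frame(sample_id = c("S1", "S2")))
    out2 <- normalizeInternalStandard(pt2, "IS")
    expect_equal(unname(heights(out2)["f", ]), c(100, 200))

    expect_error(normalizeInternalStandard(pt, "missing"), "not present")
    # IS at zero in a biological sample: error names the sample
    h3 <- h; h3[2L, 2L] <- 0
    pt3 <- PeakTable(feats, heights = h3,
                     samples = data.frame(sample_id = c("S1", "S2")))
    expect_error(normalizeInternalStandard(pt3, "IS"), "S2")
})

test_that("blank filter retains by max-biological vs mean-blank ratio", {
    feats <- data.frame(feature_id = c("hot", "bg", "absent"),
                        mz = c(100.1, 200.2, 300.3), rt = 1:3)
    h <- matrix(c(5000, 4000, 3000, 10, 9,
                  500, 400, 300, 1000, 950,
                  100, 90, 80, 0, 85),
                nrow = 3, byrow = TRUE,
                dimnames = list(NULL, bioSamples3$sample_id))
    pt <- PeakTable(feats, heights = h, samples = bioSamples3)
    out <- blankFilter(pt, filterConfig(minBlankRatio = 0.8))
    at <- attributions(out)
    expect_equal(unname(at["hot"]), "unrated")
    expect_equal(unname(at["bg"]), "interference")   # 500 < 0.8 * 1000
    expect_equal(unname(at["absent"]), "unrated")    # blank height 0

    # ratio 0 disables the filter
    out0 <- blankFilter(pt, filterConfig(minBlankRatio = 0))
    expect_true(all(attributions(out0) == "unrated"))

    # conservation: marking never adds or drops rows, never touches m/z
    expect_equal(nrow(out), nrow(pt))
    expect_identical(mz(out), mz(pt))

    # no blank declared: no-op with warning
    nb <- PeakTable(feats, heights = h[, 1:3],
                    samples = bioSamples3[1:3, ])
    expect_warning(outnb <- blankFilter(nb), "no blank")
    expect_true(all(attributions(outnb) == "unrated"))
})

test_that("RSD filter keeps features stable in at least one class", {
    samples <- data.frame(sample_id = sprintf("S%d", 1:5),
                          role = "biological",
                          class_label = c("a", "a", "a", "b", "b"))
    feats <- data.frame(feature_id = c("stable", "bestclass", "wild"),
                        mz = c(100.1, 200.2, 300.3), rt = 1:3)
    h <- matrix(c(50, 50, 50, 70, 70,        # zero RSD everywhere
                  10, 10, 10, 1, 100,        # class a RSD 0, class b huge
                  1, 100, 5, 2, 90),         # unstable in both
                nrow = 3, byrow = TRUE,
                dimnames = list(NULL, samples$sample_id))
    pt <- PeakTable(feats, heights = h, samples = samples)
    out <- rsdFilter(pt, filterConfig(maxClassRsd = 0.3))
    at <- attributions(out)
    expect_equal(unname(at), c("unrated", "unrated", "interference"))

    # hand oracle for the wild feature: both class RSDs above 0.3
    rsd <- function(v) sd(v) / mean(v)
    expect_gt(min(rsd(h[3, 1:3]), rsd(h[3, 4:5])), 0.3)

    # all-singleton classes: no-op with warning
    s1 <- data.frame(sample_id = c("S1", "S2"), role = "biological",
                     class_label = c("a", "b"))
    pt1 <- PeakTable(feats, heights = h[, 1:2], samples = s1)
    expect_warning(out1 <- rsdFilter(pt1), "no biological class")
    expect_true(all(attributions(out1) == "unrated"))
})

test_that("clustering uses the RT-and-correlation edge rule", {
    samples <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                          role = "biological", class_label = "c")
    base <- c(10, 40, 20, 80)
    feats <- data.frame(feature_id = c("A", "B", "C", "D", "E"),
                        mz = c(100.1, 150.2, 200.3, 250.4, 300.5),
                        rt = c(5.00, 5.01, 5.50, 5.02, 5.015))
    h <- rbind(A = base,               # r(A,B) = 1, co-eluting -> same cluster
               B = base * 2,
               C = base * 3,           # r = 1 but dRT 0.5 -> different cluster
               D = c(80, 20, 41, 9),   # uncorrelated with A/B
               E = c(7, 7, 7, 7))      # constant: Pearson undefined
    colnames(h) <- samples$sample_id
    pt <- PeakTable(feats, heights = h, samples = samples)
    out <- clusterFeatures(pt, filterConfig(clusterRtTol = 0.03))
    cid <- clusterIds(out)
    expect_equal(unname(cid["A"]), unname(cid["B"]))
    expect_false(cid["A"] == cid["C"])
    expect_false(cid["A"] == cid["D"])
    # constant feature ends up a singleton
    expect_false(cid["E"] %in% cid[c("A", "B", "C", "D")])
    # partition: everything clustered exactly once
    expect_false(anyNA(cid))

    # Pearson on < 3 biological samples is an error
    small <- PeakTable(feats, heights = h[, 1:2],
                       samples = samples[1:2, ])
    expect_error(clusterFeatures(small), ">= 3 biological")
})

test_that("clustering takes the transitive closure of edges", {
    samples <- data.frame(sample_id = sprintf("S%d", 1:4),
                          role = "biological", class_label = "c")
    # A-B correlated, B-C correlated, A-C below threshold; all co-eluting
    h <- rbind(A = c(3.4, 5.7, 6.5, 2.1),
               B = c(5, 7.9, 7.1, 0.4),
               C = c(8.2, 8.1, 7.3, 1.9))
    # fixture sanity: edges A-B and B-C exist at r >= 0.9, A-C does not
    expect_gte(cor(h["A", ], h["B", ]), 0.9)
    expect_gte(cor(h["B", ], h["C", ]), 0.9)
    expect_lt(cor(h["A", ], h["C", ]), 0.9)
    feats <- data.frame(feature_id = c("A", "B", "C"),
                        mz = c(100.1, 150.2, 200.3), rt = 5)
    colnames(h) <- samples$sample_id
    pt <- PeakTable(feats, heights = h, samples = samples)
    out <- clusterFeatures(pt, filterConfig(minPearson = 0.9))
    cid <- clusterIds(out)
    # connected components take the transitive closure: one 3-member cluster
    expect_equal(length(unique(cid)), 1L)
})

test_that("clustering is permutation-invariant and coarsens monotonically", {
    sim <- simulatePeakTable(simConfig(nCompounds = 15, nNoiseFeatures = 5,
                                       seed = 5))
    pt <- sim$table
    cfg <- filterConfig(minPearson = 0.8, clusterRtTol = 0.03)
    out1 <- clusterFeatures(pt, cfg)
    perm <- sample(nrow(pt))
    out2 <- clusterFeatures(pt[perm, ], cfg)
    ids <- featureIds(pt)
    expect_identical(clusterIds(out1)[ids], clusterIds(out2)[ids])

    # lowering the correlation threshold never splits a cluster
    loose <- clusterFeatures(pt, filterConfig(minPearson = 0.5,
                                              clusterRtTol = 0.06))
    tight_cl <- split(ids, clusterIds(out1)[ids])
    loose_map <- clusterIds(loose)[ids]
    for (grp in tight_cl)
        expect_equal(length(unique(loose_map[grp])), 1L)
})
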