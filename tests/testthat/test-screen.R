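test_that("per-replicate ratios are exact quotients of their channels", {
    se <- makeLSE(list(
        FLAT = list(rep1 = channels(100)),
        P = list(rep1 = channels(100,
                                 WT_T0 = 100, WT_T30 = 50,
                                 DLON_T0 = 130, DLON_T30 = 125,
                                 DEPL_NO_VAN = 120, DEPL_PLUS_VAN = 100,
                                 OE_GLUC = 110, OE_XYL1H = 100))),
        replicates = "rep1")
    r <- computeRatios(se)
    expect_equal(unname(r["FLAT", "rep1", ]), rep(1, 5))
    expect_equal(r["P", "rep1", ],
                 c(r_steady = 1.3, r_depl = 1.2, r_oe = 1.1,
                   r_wt_decay = 2.0, r_dlon_decay = 1.04))
})

test_that("a missing channel silently removes only the ratios that need it", {
    se <- makeLSE(list(
        P = list(rep1 = channels(100),
                 rep2 = channels(100)[setdiff(lonChannels(), "WT_T30")])))
    r <- computeRatios(se)
    expect_true(is.na(r["P", "rep2", "r_wt_decay"]))
    expect_equal(sum(is.na(r)), 1L)
})

test_that("replicate aggregation averages, falls back, and derives stabilization", {
    se <- makeLSE(list(
        # r_steady 1.2 in rep1, 1.4 in rep2
        AVG = list(rep1 = channels(100, DLON_T0 = 120, DLON_T15 = 120,
                                   DLON_T30 = 120),
                   rep2 = channels(100, DLON_T0 = 140, DLON_T15 = 140,
                                   DLON_T30 = 140)),
        # detected in rep1 only, r_steady 1.25
        SINGLE = list(rep1 = channels(100, DLON_T0 = 125, DLON_T15 = 125,
                                      DLON_T30 = 125)),
        # aggregated r_wt_decay 2.0, r_dlon_decay 1.04
        STAB = list(rep1 = channels(100, WT_T30 = 50, DLON_T30 = 100 / 1.04),
                    rep2 = channels(100, WT_T30 = 50, DLON_T30 = 100 / 1.04))))
    m <- aggregateReplicates(computeRatios(se))
    rownames(m) <- m$protein_id
    expect_equal(m["AVG", "r_steady"], 1.3)
    expect_equal(m["AVG", "prov_r_steady"], "both_replicates")
    expect_equal(m["SINGLE", "r_steady"], 1.25)
    expect_equal(m["SINGLE", "prov_r_steady"], "single_replicate")
    expect_equal(m["STAB", "r_stabilization"], 2.0 / 1.04)
})

test_that("stab_mode controls how the ratio-of-ratios is formed", {
    # decay ratios differ between replicates so the two modes disagree
    se <- makeLSE(list(
        P = list(rep1 = channels(100, WT_T30 = 50, DLON_T30 = 100),
                 rep2 = channels(100, WT_T30 = 25, DLON_T30 = 50))))
    r <- computeRatios(se)
    fromMeans <- aggregateReplicates(r, stab_mode = "from_means")
    perRep <- aggregateReplicates(r, stab_mode = "per_replicate_mean")
    expect_equal(fromMeans$r_stabilization, mean(c(2, 4)) / mean(c(1, 2)))
    expect_equal(perRep$r_stabilization, mean(c(2 / 1, 4 / 2)))
})

test_that("criteria are inclusive thresholds with a gated stabilization test", {
    means <- data.frame(
        protein_id = c("NULLP", "ALL4", "EDGE", "NOGATE", "NAROW"),
        r_steady = c(1, 1.3, 1.1, 1.3, NA),
        r_depl = c(1, 1.2, 1.1, 1.2, 1.2),
        r_oe = c(1, 1.1, 1.05, 1.1, 1.1),
        r_wt_decay = c(1, 2, 1, 0.9, 2),
        r_dlon_decay = c(1, 1.04, 1, 0.8, 1),
        r_stabilization = c(1, 2 / 1.04, 1.05, 0.9 / 0.8, 2))
    fl <- applyCriteria(means, criteriaThresholds())
    rownames(fl) <- fl$protein_id
    # flat profile: the wt-decay gate passes at 1 >= 1 but 1.0 < 1.05
    expect_equal(unlist(fl["NULLP", c("c_steady", "c_depl", "c_oe", "c_stab")]),
                 c(c_steady = FALSE, c_depl = FALSE, c_oe = FALSE,
                   c_stab = FALSE))
    expect_equal(fl["ALL4", "n_criteria"], 4L)
    # comparisons are inclusive: exactly-at-threshold passes
    expect_equal(fl["EDGE", "n_criteria"], 4L)
    # stabilization requires net wild-type decay even if the ratio passes
    expect_false(fl["NOGATE", "c_stab"])
    expect_equal(fl["NOGATE", "n_criteria"], 3L)
    # missing mean ratio means the criterion is false, not an error
    expect_false(fl["NAROW", "c_steady"])
    expect_equal(fl["NAROW", "n_criteria"], 3L)
})

test_that("putative calls require min_criteria of the four flags", {
    fm <- rbind("T3" = c(TRUE, TRUE, TRUE, FALSE),
                "T2" = c(TRUE, TRUE, FALSE, FALSE))
    colnames(fm) <- c("c_steady", "c_depl", "c_oe", "c_stab")
    means <- data.frame(protein_id = rownames(fm),
                        r_steady = 1, r_depl = 1, r_oe = 1,
                        r_wt_decay = 1, r_dlon_decay = 1,
                        r_stabilization = 1)
    tab <- selectCandidates(means, flagsFromMatrix(fm))
    expect_equal(tab$putative, c(TRUE, FALSE))
    tab4 <- selectCandidates(means, flagsFromMatrix(fm),
                             criteriaThresholds(min_criteria = 4))
    expect_equal(tab4$putative, c(FALSE, FALSE))
    # every detected protein appears, candidates or not
    expect_equal(nrow(tab), 2L)
})

test_that("venn counts match the worked 3-protein example and the trivial case", {
    fm <- rbind(A = c(TRUE, TRUE, TRUE, TRUE),
                B = c(TRUE, TRUE, TRUE, FALSE),
                C = c(TRUE, FALSE, FALSE, FALSE))
    colnames(fm) <- c("c_steady", "c_depl", "c_oe", "c_stab")
    v <- vennCounts(flagsFromMatrix(fm))
    expect_equal(vennRegions(v)[["steady+depl+oe+stab"]], 1L)
    expect_equal(vennRegions(v)[["steady+depl+oe"]], 1L)
    expect_equal(vennRegions(v)[["steady"]], 1L)
    expect_equal(sum(vennRegions(v)), 3L)
    expect_equal(vennByK(v), c("4" = 1L, "3" = 1L, "2" = 0L, "1" = 1L))

    none <- matrix(FALSE, 5, 4,
                   dimnames = list(paste0("P", 1:5),
                                   c("c_steady", "c_depl", "c_oe", "c_stab")))
    v0 <- vennCounts(flagsFromMatrix(none))
    expect_true(all(vennRegions(v0) == 0L))
    expect_equal(vennZero(v0), 5L)
})

test_that("venn counts equal brute-force subset enumeration on all 16 patterns", {
    fm <- allFlagPatterns()
    v <- vennCounts(flagsFromMatrix(fm))
    oracle <- bruteVenn(fm)
    expect_equal(vennRegions(v)[names(oracle)], oracle)
    expect_equal(vennZero(v), 1L)
})

test_that("detected-protein counts are per replicate", {
    se <- makeLSE(list(P1 = list(rep1 = channels(1), rep2 = channels(2)),
                       P2 = list(rep1 = channels(3), rep2 = channels(4)),
                       P3 = list(rep1 = channels(5))))
    expect_equal(countDetected(se, "rep1"), 3L)
    expect_equal(countDetected(se, "rep2"), 2L)
    expect_error(countDetected(se, "rep9"), "unknown replicate")

    empty <- LonScreenExperiment(
        matrix(numeric(0), nrow = 0, ncol = 20,
               dimnames = list(character(0), NULL)),
        replicate = rep(c("rep1", "rep2"), each = 10),
        channel = rep(lonChannels(), 2))
    expect_equal(countDetected(empty, "rep1"), 0L)
})

test_that("threshold validation enforces the documented ranges", {
    expect_error(criteriaThresholds(theta_steady = 0.9), ">= 1")
    expect_error(criteriaThresholds(min_criteria = 5), "min_criteria")
    expect_s4_class(criteriaThresholds(min_criteria = 1), "CriteriaThresholds")
})
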