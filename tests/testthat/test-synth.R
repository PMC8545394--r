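test_that("noiseless planted classes produce exactly the analytic ratios", {
    sim <- simulateScreenData(
        simulationParams(n_substrates = 5, n_stable_nonsubstrates = 5,
                         n_nonlon_unstable = 5,
                         noise_sigma = 0, dropout_p = 0),
        seed = 1)
    res <- screenSubstrates(sim$experiment)
    tab <- res$candidates
    cls <- sim$truth$class[match(tab$protein_id, sim$truth$protein_id)]

    sub <- tab[cls == "lon_substrate", ]
    expect_equal(sub$r_steady, rep(1.5, 5))
    expect_equal(sub$r_depl, rep(1.5, 5))
    expect_equal(sub$r_oe, rep(1 / 0.67, 5))
    expect_equal(sub$r_wt_decay, rep(exp(log(2) * 30 / 12), 5))
    expect_equal(sub$r_stabilization, rep(exp(log(2) * 30 / 12), 5))
    expect_equal(sub$n_criteria, rep(4L, 5))
    expect_true(all(sub$putative))

    expect_true(all(tab$n_criteria[cls == "stable_nonsubstrate"] == 0L))

    # symmetric Lon-independent decay cancels in the stabilization ratio
    # and leaves the endpoint ratios flat
    unst <- tab[cls == "nonlon_unstable", ]
    expect_equal(unst$r_stabilization, rep(1, 5))
    expect_false(any(unst$c_stab | unst$c_steady | unst$c_depl | unst$c_oe))
    expect_true(all(unst$r_wt_decay > 1))  # they do decay, in both strains
})

test_that("generation is seed-deterministic", {
    p <- simulationParams(n_substrates = 10, n_stable_nonsubstrates = 10,
                          n_nonlon_unstable = 5)
    a <- simulateScreenData(p, seed = 42)
    b <- simulateScreenData(p, seed = 42)
    expect_identical(abundances(a$experiment), abundances(b$experiment))
    expect_identical(a$truth, b$truth)
    c <- simulateScreenData(p, seed = 43)
    expect_true(any(abundances(a$experiment) != abundances(c$experiment),
                    na.rm = TRUE))
})

test_that("class proportions match the parameters exactly", {
    sim <- simulateScreenData(
        simulationParams(n_substrates = 7, n_stable_nonsubstrates = 13,
                         n_nonlon_unstable = 3),
        seed = 2)
    expect_equal(as.vector(table(factor(sim$truth$class,
                                        c("lon_substrate",
                                          "stable_nonsubstrate",
                                          "nonlon_unstable")))),
                 c(7L, 13L, 3L))
})

test_that("with noise the mean log ratio converges to the planted log effect", {
    n <- 400
    sigma <- 0.1
    sim <- simulateScreenData(
        simulationParams(n_substrates = n, n_stable_nonsubstrates = 0,
                         n_nonlon_unstable = 0,
                         noise_sigma = sigma, dropout_p = 0),
        seed = 3)
    r <- computeRatios(sim$experiment)
    # per-replicate log ratio has SD sigma*sqrt(2); tolerance 3*sd/sqrt(n)
    tol <- 3 * sigma * sqrt(2) / sqrt(n)
    expect_lt(abs(mean(log(r[, , "r_steady"])) - log(1.5)), tol)
    expect_lt(abs(mean(log(r[, , "r_oe"])) - log(1 / 0.67)), tol)
    expect_lt(abs(mean(log(r[, , "r_wt_decay"])) - log(2) * 30 / 12), tol)
})

test_that("dropout reproduces whole-replicate missingness at the stated rate", {
    sim <- simulateScreenData(
        simulationParams(n_substrates = 0, n_stable_nonsubstrates = 2000,
                         n_nonlon_unstable = 0, dropout_p = 0.05),
        seed = 4)
    mask <- detectionMask(sim$experiment)
    # a dropped (protein, replicate) has no channel at all
    a <- abundances(sim$experiment)
    miss1 <- rowSums(is.na(a[, 1:10]))
    expect_true(all(miss1 %in% c(0L, 10L)))
    rate <- mean(!mask)
    expect_gt(rate, 0.03)
    expect_lt(rate, 0.07)
})

test_that("parameter validation rejects invalid worlds before sampling", {
    expect_error(simulationParams(n_substrates = -1), "non-negative")
    expect_error(simulationParams(f_oe = 1.5), "f_oe")
    expect_error(simulationParams(dropout_p = 1), "dropout_p")
    expect_error(simulationParams(noise_sigma = -0.1), "noise_sigma")
})

test_that("fixtures written to disk rerun the screen identically", {
    dir <- withr::local_tempdir()
    p <- simulationParams(n_substrates = 6, n_stable_nonsubstrates = 10,
                          n_nonlon_unstable = 2)
    paths <- writeFixture(p, dir, seed = 9)
    expect_true(all(file.exists(paths)))
    sim <- simulateScreenData(p, seed = 9)
    expect_equal(nrow(utils::read.delim(paths["truth"])), 18L)
    back <- readAbundanceTable(paths["abundance"], dialect = "wide")
    expect_equal(abundances(back), abundances(sim$experiment))
})
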