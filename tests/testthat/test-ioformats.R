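test_that("wide abundance tables round-trip and record detection", {
    se <- makeLSE(list(
        P1 = list(rep1 = channels(100), rep2 = channels(110)),
        P2 = list(rep1 = channels(200, WT_T0 = 250),
                  rep2 = channels(210)),
        P3 = list(rep1 = channels(50), rep2 = channels(60))))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeAbundanceTable(se, path, dialect = "wide")
    back <- readAbundanceTable(path, dialect = "wide")
    expect_equal(abundances(back), abundances(se))
    expect_true(all(detectionMask(back)))
    expect_equal(nrow(back), 3L)
})

test_that("a protein measured in one replicate only is undetected in the other", {
    # mirrors the screen's single-replicate case (a MotD-like protein)
    se <- makeLSE(list(
        "MotD-like" = list(rep1 = channels(100)),
        P2 = list(rep1 = channels(10), rep2 = channels(12))))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeAbundanceTable(se, path)
    mask <- detectionMask(readAbundanceTable(path))
    expect_false(mask["MotD-like", "rep2"])
    expect_true(mask["MotD-like", "rep1"])
    expect_true(all(mask["P2", ]))
})

test_that("long dialect round-trips to the same matrix as wide", {
    se <- makeLSE(list(
        P1 = list(rep1 = channels(100, WT_T30 = 40), rep2 = channels(90)),
        P2 = list(rep2 = channels(5))))
    long <- withr::local_tempfile(fileext = ".tsv")
    wide <- withr::local_tempfile(fileext = ".tsv")
    writeAbundanceTable(se, long, dialect = "long")
    fromLong <- readAbundanceTable(long, dialect = "long")
    writeAbundanceTable(fromLong, wide, dialect = "wide")
    fromWide <- readAbundanceTable(wide, dialect = "wide")
    expect_equal(abundances(fromWide), abundances(fromLong))
    expect_equal(abundances(fromLong), abundances(se))
})

test_that("parsing is row-order independent", {
    se <- makeLSE(list(P1 = list(rep1 = channels(1), rep2 = channels(2)),
                       P2 = list(rep1 = channels(3), rep2 = channels(4)),
                       P3 = list(rep1 = channels(5), rep2 = channels(6))))
    path <- withr::local_tempfile(fileext = ".tsv")
    shuffled <- withr::local_tempfile(fileext = ".tsv")
    writeAbundanceTable(se, path)
    lines <- readLines(path)
    writeLines(c(lines[1], lines[c(4, 2, 3)]), shuffled)
    back <- readAbundanceTable(shuffled)
    expect_equal(abundances(back)[rownames(se), ], abundances(se))
})

test_that("missing-value encodings and format errors are handled", {
    path <- withr::local_tempfile(fileext = ".tsv")
    hdr <- paste(c("protein_id", paste("rep1", lonChannels(), sep = ":")),
                 collapse = "\t")
    row <- function(id, vals) paste(c(id, vals), collapse = "\t")

    # blank, "NA" and "0" all read as missing
    writeLines(c(hdr, row("P1", c("", "NA", "0", rep("10", 7)))), path)
    a <- abundances(readAbundanceTable(path))
    expect_equal(sum(is.na(a["P1", ])), 3L)
    expect_equal(unname(a["P1", "rep1:DLON_T0"]), 10)

    # unknown channel label names the offending column
    writeLines(c(sub("rep1:WT_T0", "rep1:BOGUS", hdr),
                 row("P1", rep("1", 10))), path)
    expect_error(readAbundanceTable(path), "rep1:BOGUS")

    # duplicate protein rows
    writeLines(c(hdr, row("P1", rep("1", 10)), row("P1", rep("2", 10))),
               path)
    expect_error(readAbundanceTable(path), "duplicate")

    # non-numeric cell reported with its row number
    writeLines(c(hdr, row("P1", rep("1", 10)),
                 row("P2", c("abc", rep("1", 9)))), path)
    expect_error(readAbundanceTable(path), "row 3")
})

test_that("candidate tables round-trip with the fixed column order", {
    sim <- simulateScreenData(simulationParams(n_substrates = 4,
                                               n_stable_nonsubstrates = 6,
                                               n_nonlon_unstable = 2,
                                               dropout_p = 0),
                              seed = 5)
    tab <- screenSubstrates(sim$experiment)$candidates
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCandidates(tab, path)
    back <- readCandidates(path)
    expect_equal(back, tab, tolerance = 1e-12)
    expect_equal(colnames(back),
                 c("protein_id", "r_steady", "r_depl", "r_oe",
                   "r_wt_decay", "r_stabilization",
                   "c_steady", "c_depl", "c_oe", "c_stab",
                   "n_criteria", "putative", "category"))
})

test_that("candidate files have one data line per protein, header-only when empty", {
    sim <- simulateScreenData(simulationParams(n_substrates = 73,
                                               n_stable_nonsubstrates = 73,
                                               n_nonlon_unstable = 0,
                                               dropout_p = 0),
                              seed = 6)
    tab <- screenSubstrates(sim$experiment)$candidates
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCandidates(tab, path)
    expect_length(readLines(path), 146L + 1L)

    writeCandidates(tab[0, ], path)
    expect_length(readLines(path), 1L)
})

test_that("category maps read, collapse duplicates and reject conflicts", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("protein_id\tcategory",
                 "P1\tcell cycle", "P2\tmotility"), path)
    map <- readCategoryMap(path)
    expect_equal(map, c(P1 = "cell cycle", P2 = "motility"))

    writeLines(c("protein_id\tcategory",
                 "P1\tcell cycle", "P1\tcell cycle", "P2\tmotility"), path)
    expect_length(readCategoryMap(path), 2L)

    writeLines(c("protein_id\tcategory",
                 "P1\tcell cycle", "P1\tmotility"), path)
    expect_error(readCategoryMap(path), "conflicting")
})
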