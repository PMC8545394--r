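# Fixture builders and independent oracles shared across the suite.

# Build a LonScreenExperiment from a nested list:
# values[[protein]][[replicate]] = named numeric vector of channel values
# (channels omitted from the vector are missing).
makeLSE <- function(values, replicates = c("rep1", "rep2")) {
    proteins <- names(values)
    mat <- matrix(NA_real_,
                  nrow = length(proteins),
                  ncol = length(replicates) * 10L,
                  dimnames = list(proteins,
                                  paste(rep(replicates, each = 10L),
                                        rep(lonChannels(),
                                            length(replicates)),
                                        sep = ":")))
    for (p in proteins) {
        for (r in names(values[[p]])) {
            v <- values[[p]][[r]]
            mat[p, paste(r, names(v), sep = ":")] <- v
        }
    }
    LonScreenExperiment(mat,
                        replicate = rep(replicates, each = 10L),
                        channel = rep(lonChannels(), length(replicates)))
}

# Named channel vector with every channel at `base`, overridden by ...
channels <- function(base = 100, ...) {
    v <- stats::setNames(rep(base, 10L), lonChannels())
    over <- c(...)
    v[names(over)] <- over
    v
}

# Random fully-observed experiment for property tests.
randomExperiment <- function(n = 8, seed = 1, missing_frac = 0) {
    set.seed(seed)
    mat <- matrix(exp(rnorm(n * 20, mean = log(1e5), sd = 1)),
                  nrow = n,
                  dimnames = list(sprintf("P%03d", seq_len(n)), NULL))
    if (missing_frac > 0)
        mat[runif(length(mat)) < missing_frac] <- NA_real_
    # keep at least one value per protein so everything stays detected
    mat[, 1][is.na(mat[, 1])] <- 1
    LonScreenExperiment(mat,
                        replicate = rep(c("rep1", "rep2"), each = 10L),
                        channel = rep(lonChannels(), 2L))
}

# Independent brute-force Venn oracle: for every subset S of the four
# criterion sets, count proteins whose TRUE-flag set is exactly S.
bruteVenn <- function(fm) {
    labels <- c("steady", "depl", "oe", "stab")
    out <- integer(0)
    for (k in 1:4) {
        for (s in utils::combn(4L, k, simplify = FALSE)) {
            nm <- paste(labels[s], collapse = "+")
            hit <- apply(fm, 1L, function(row)
                all(row[s]) && !any(row[setdiff(1:4, s)]))
            out[nm] <- sum(hit)
        }
    }
    out
}

# All 16 possible flag patterns as a logical matrix (one protein each).
allFlagPatterns <- function() {
    fm <- as.matrix(expand.grid(c_steady = c(FALSE, TRUE),
                                c_depl = c(FALSE, TRUE),
                                c_oe = c(FALSE, TRUE),
                                c_stab = c(FALSE, TRUE)))
    rownames(fm) <- sprintf("PAT%02d", seq_len(nrow(fm)))
    fm
}

flagsFromMatrix <- function(fm) {
    data.frame(protein_id = rownames(fm),
               c_steady = fm[, 1], c_depl = fm[, 2],
               c_oe = fm[, 3], c_stab = fm[, 4],
               n_criteria = as.integer(rowSums(fm)),
               row.names = NULL, stringsAsFactors = FALSE)
}
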