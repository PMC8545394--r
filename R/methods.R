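#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats lm coef runif sd setNames rlnorm
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Accessors for LonScreenExperiment
#'
#' `replicates()` returns the replicate identifiers, `abundances()` the
#' abundance matrix (proteins x replicate:channel columns, `NA` = not
#' measured), `detectionMask()` the proteins x replicates logical matrix of
#' detection (a protein is detected in a replicate if any channel of that
#' replicate was measured), and `detectedProteins()` the identifiers of
#' proteins detected in at least one replicate (the screen's universe).
#'
#' @param x a [LonScreenExperiment-class].
#' @return See individual descriptions.
#' @examples
#' sim <- simulateScreenData(simulationParams(n_substrates = 5,
#'                                            n_stable_nonsubstrates = 5,
#'                                            n_nonlon_unstable = 0),
#'                           seed = 1)
#' replicates(sim$experiment)
#' head(detectionMask(sim$experiment))
#' @name lonscreen-accessors
NULL

#' @rdname lonscreen-accessors
#' @export
replicates <- function(x) {
    stopifnot(methods::is(x, "LonScreenExperiment"))
    unique(as.character(SummarizedExperiment::colData(x)$replicate))
}

#' @rdname lonscreen-accessors
#' @export
abundances <- function(x) {
    stopifnot(methods::is(x, "LonScreenExperiment"))
    SummarizedExperiment::assay(x, "abundance")
}

#' @rdname lonscreen-accessors
#' @export
detectionMask <- function(x) {
    a <- abundances(x)
    reps <- replicates(x)
    cd <- SummarizedExperiment::colData(x)
    mask <- matrix(FALSE, nrow(a), length(reps),
                   dimnames = list(rownames(x), reps))
    for (r in reps) {
        cols <- which(cd$replicate == r)
        mask[, r] <- rowSums(!is.na(a[, cols, drop = FALSE])) > 0
    }
    mask
}

#' @rdname lonscreen-accessors
#' @export
detectedProteins <- function(x) {
    mask <- detectionMask(x)
    rownames(mask)[rowSums(mask) > 0]
}

#' Number of proteins detected in one replicate
#'
#' A protein counts as detected in a replicate if it has at least one
#' measured channel there; the published screen reports this pair of counts
#' (2270 and 2261 in its two biological replicates).
#'
#' @param x a [LonScreenExperiment-class].
#' @param replicate a replicate identifier present in `x`.
#' @return Integer count.
#' @export
countDetected <- function(x, replicate) {
    mask <- detectionMask(x)
    if (!replicate %in% colnames(mask))
        stop("unknown replicate: '", replicate, "'")
    sum(mask[, replicate])
}

setMethod("show", "LonScreenExperiment", function(object) {
    cat("LonScreenExperiment:", nrow(object), "proteins,",
        length(replicates(object)), "replicate(s) x",
        length(lonChannels()), "channels\n")
    mask <- detectionMask(object)
    for (r in colnames(mask))
        cat("  detected in", r, ":", sum(mask[, r]), "\n")
    methods::callNextMethod()
})

setMethod("show", "CriteriaThresholds", function(object) {
    cat("CriteriaThresholds\n")
    cat(sprintf("  steady state (dlon0/wt0)        >= %.3g\n",
                object@theta_steady))
    cat(sprintf("  depletion (no van/+van)         >= %.3g\n",
                object@theta_depl))
    cat(sprintf("  overexpression (gluc/+xyl)      >= %.3g\n",
                object@theta_oe))
    cat(sprintf("  stabilization: wt0/wt30 >= %.3g and ratio-of-ratios >= %.3g\n",
                object@theta_wt_decay_gate, object@theta_stab))
    cat(sprintf("  putative if >= %d of 4 criteria; stab_mode = %s\n",
                object@min_criteria, object@stab_mode))
})

setMethod("show", "VennCounts", function(object) {
    cat("VennCounts over criterion sets {steady, depl, oe, stab}\n")
    cat("  by number of criteria met:",
        paste(sprintf("%s:%d", names(object@by_k), object@by_k),
              collapse = "  "), "\n")
    cat("  meeting none:", object@n_zero, "\n")
    nz <- object@regions[object@regions > 0]
    if (length(nz)) {
        cat("  non-empty exclusive regions:\n")
        for (i in seq_along(nz))
            cat(sprintf("    %-24s %d\n", names(nz)[i], nz[i]))
    }
})

setMethod("show", "HalfLifeEstimate", function(object) {
    if (isStable(object)) {
        cat(sprintf("HalfLifeEstimate: stable (k = %.4g/min <= 0, no net decay)\n",
                    object@k))
    } else {
        cat(sprintf("HalfLifeEstimate: t1/2 = %.4g min (k = %.4g/min)\n",
                    object@t_half, object@k))
    }
    cat(sprintf("  log-linear fit on %d points; R^2 = %s\n",
                object@n_points,
                ifelse(is.na(object@r_squared), "NA",
                       sprintf("%.4f", object@r_squared))))
})

#' @rdname fitHalfLife
#' @param object a [HalfLifeEstimate-class].
#' @export
isStable <- function(object) {
    stopifnot(methods::is(object, "HalfLifeEstimate"))
    object@k <= 0
}

#' @rdname fitHalfLife
#' @export
halfLife <- function(object) {
    stopifnot(methods::is(object, "HalfLifeEstimate"))
    object@t_half
}

#' @rdname fitHalfLife
#' @export
decayConstant <- function(object) {
    stopifnot(methods::is(object, "HalfLifeEstimate"))
    object@k
}

#' Accessors for VennCounts
#'
#' `vennRegions()` returns the 15 exclusive region counts, `vennByK()` the
#' counts of proteins meeting exactly 4/3/2/1 criteria, `vennZero()` the
#' count meeting none.
#'
#' @param object a [VennCounts-class].
#' @return Named integer vector (or single integer for `vennZero`).
#' @name venn-accessors
NULL

#' @rdname venn-accessors
#' @export
vennRegions <- function(object) {
    stopifnot(methods::is(object, "VennCounts"))
    object@regions
}

#' @rdname venn-accessors
#' @export
vennByK <- function(object) {
    stopifnot(methods::is(object, "VennCounts"))
    object@by_k
}

#' @rdname venn-accessors
#' @export
vennZero <- function(object) {
    stopifnot(methods::is(object, "VennCounts"))
    object@n_zero
}
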