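#' The ten condition channels of the substrate screen
#'
#' The screen quantifies each protein in ten strain/condition channels of a
#' TMT10 plex, one plex per biological replicate: wild type and \emph{lon}
#' deletion sampled 0, 15 and 30 minutes after translation shut-off, a
#' vanillate-driven Lon depletion strain with and without inducer, and a
#' xylose-driven \emph{lon} overexpression strain before (glucose) and 1 hour
#' after induction.
#'
#' @return Character vector of the ten channel labels, in canonical order.
#' @examples
#' lonChannels()
#' @export
lonChannels <- function() {
    c("WT_T0", "WT_T15", "WT_T30",
      "DLON_T0", "DLON_T15", "DLON_T30",
      "DEPL_PLUS_VAN", "DEPL_NO_VAN",
      "OE_GLUC", "OE_XYL1H")
}

#' @rdname lonChannels
#' @return `ratioNames()` returns the names of the five per-replicate
#'   condition ratios derived from the channels.
#' @export
ratioNames <- function() {
    c("r_steady", "r_depl", "r_oe", "r_wt_decay", "r_dlon_decay")
}

#' LonScreenExperiment: protein abundances across replicates and channels
#'
#' A \linkS4class{SummarizedExperiment} whose single `"abundance"` assay
#' holds strictly positive reporter intensities for proteins (rows) across
#' the replicate-by-channel sample grid (columns). Missing measurements are
#' `NA` -- never 0, since every downstream quantity is a ratio. `colData`
#' carries the `replicate` and `channel` of each column; the grid is always
#' complete (every replicate has a column for each of the ten channels).
#'
#' A protein is \emph{detected} in a replicate if it has at least one
#' non-missing value in that replicate's channels; see [detectionMask()].
#'
#' @seealso [LonScreenExperiment()] the constructor, [readAbundanceTable()],
#'   [computeRatios()]
#' @aliases LonScreenExperiment-class
#' @exportClass LonScreenExperiment
setClass("LonScreenExperiment", contains = "SummarizedExperiment")

setValidity("LonScreenExperiment", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("replicate", "channel") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'replicate' and 'channel'")
    if (length(msg))
        return(msg)
    bad <- setdiff(unique(as.character(cd$channel)), lonChannels())
    if (length(bad))
        msg <- c(msg, paste0("unknown channel label(s): ",
                             paste(bad, collapse = ", ")))
    key <- paste(cd$replicate, cd$channel, sep = ":")
    if (anyDuplicated(key))
        msg <- c(msg, "duplicated (replicate, channel) columns")
    reps <- unique(as.character(cd$replicate))
    if (nrow(cd) != length(reps) * length(lonChannels()))
        msg <- c(msg, "replicate x channel grid must be complete")
    a <- SummarizedExperiment::assay(object, "abundance")
    if (!is.numeric(a))
        msg <- c(msg, "abundances must be numeric")
    else if (any(a <= 0, na.rm = TRUE))
        msg <- c(msg, "abundances must be strictly positive (use NA for missing)")
    rn <- rownames(object)
    if (nrow(object) > 0L &&
        (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn))))
        msg <- c(msg, "rownames must be unique non-empty protein identifiers")
    if (length(msg)) msg else TRUE
})

#' Construct a LonScreenExperiment
#'
#' @param abundance numeric matrix, proteins x samples, strictly positive
#'   with `NA` for unmeasured cells. Rownames are protein identifiers.
#' @param replicate character vector, one entry per column of `abundance`.
#' @param channel character vector of channel labels per column; must be
#'   drawn from [lonChannels()]. Every replicate must cover all ten
#'   channels (columns with no measurements should be all-`NA`, not absent).
#' @return A [LonScreenExperiment-class] object with columns ordered
#'   replicate-major in canonical channel order.
#' @examples
#' m <- matrix(100, 2, 20,
#'             dimnames = list(c("P1", "P2"), NULL))
#' se <- LonScreenExperiment(m,
#'                           replicate = rep(c("rep1", "rep2"), each = 10),
#'                           channel = rep(lonChannels(), 2))
#' se
#' @export
LonScreenExperiment <- function(abundance, replicate, channel) {
    abundance <- as.matrix(abundance)
    storage.mode(abundance) <- "double"
    if (length(replicate) != ncol(abundance) ||
        length(channel) != ncol(abundance))
        stop("'replicate' and 'channel' must have one entry per column")
    replicate <- as.character(replicate)
    channel <- as.character(channel)
    ord <- order(match(replicate, unique(replicate)),
                 match(channel, lonChannels()))
    abundance <- abundance[, ord, drop = FALSE]
    replicate <- replicate[ord]
    channel <- channel[ord]
    colnames(abundance) <- paste(replicate, channel, sep = ":")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = abundance),
        colData = S4Vectors::DataFrame(replicate = replicate,
                                       channel = channel,
                                       row.names = colnames(abundance)))
    methods::new("LonScreenExperiment", se)
}

#' Thresholds of the four-criterion substrate screen
#'
#' Holds the ratio thresholds used to call the four substrate criteria, the
#' minimum number of criteria for a putative-substrate call, and the mode
#' used to combine the decay ratios into the stabilization ratio. Defaults
#' reproduce the published screen: steady-state and depletion ratios at
#' 1.1, overexpression ratio at 1.05, the stabilization criterion gated on
#' wild-type decay >= 1 with the ratio-of-ratios at 1.05, and at least
#' three of four criteria required. Thresholds are deliberately low because
#' TMT reporter ratios have a compressed dynamic range.
#'
#' @slot theta_steady threshold on DLON_T0/WT_T0 (dimensionless, >= 1).
#' @slot theta_depl threshold on DEPL_NO_VAN/DEPL_PLUS_VAN.
#' @slot theta_oe threshold on OE_GLUC/OE_XYL1H.
#' @slot theta_wt_decay_gate gate on WT_T0/WT_T30 before the stabilization
#'   ratio is considered.
#' @slot theta_stab threshold on (WT_T0/WT_T30)/(DLON_T0/DLON_T30).
#' @slot min_criteria integer in 1..4; proteins meeting at least this many
#'   criteria are putative substrates.
#' @slot stab_mode `"from_means"` (default: ratio of the replicate-averaged
#'   decay ratios) or `"per_replicate_mean"` (average of per-replicate
#'   ratios-of-ratios).
#' @aliases CriteriaThresholds-class
#' @seealso [criteriaThresholds()], [applyCriteria()]
#' @exportClass CriteriaThresholds
setClass("CriteriaThresholds",
         representation(theta_steady = "numeric",
                        theta_depl = "numeric",
                        theta_oe = "numeric",
                        theta_wt_decay_gate = "numeric",
                        theta_stab = "numeric",
                        min_criteria = "integer",
                        stab_mode = "character"))

setValidity("CriteriaThresholds", function(object) {
    th <- c(object@theta_steady, object@theta_depl, object@theta_oe,
            object@theta_wt_decay_gate, object@theta_stab)
    if (length(th) != 5L || any(!is.finite(th)))
        return("all five thresholds must be single finite numbers")
    if (any(th < 1))
        return("all thresholds must be >= 1")
    if (length(object@min_criteria) != 1L ||
        !object@min_criteria %in% 1:4)
        return("min_criteria must be a single integer in 1..4")
    if (!object@stab_mode %in% c("from_means", "per_replicate_mean"))
        return("stab_mode must be 'from_means' or 'per_replicate_mean'")
    TRUE
})

#' @param theta_steady,theta_depl,theta_oe,theta_wt_decay_gate,theta_stab
#'   ratio thresholds, all >= 1; see the class slots.
#' @param min_criteria integer in 1..4.
#' @param stab_mode `"from_means"` or `"per_replicate_mean"`.
#' @return `criteriaThresholds()` returns a validated
#'   [CriteriaThresholds-class] object.
#' @examples
#' criteriaThresholds()
#' criteriaThresholds(min_criteria = 4)
#' @rdname CriteriaThresholds-class
#' @export
criteriaThresholds <- function(theta_steady = 1.1,
                               theta_depl = 1.1,
                               theta_oe = 1.05,
                               theta_wt_decay_gate = 1.0,
                               theta_stab = 1.05,
                               min_criteria = 3L,
                               stab_mode = c("from_means",
                                             "per_replicate_mean")) {
    stab_mode <- match.arg(stab_mode)
    methods::new("CriteriaThresholds",
                 theta_steady = as.numeric(theta_steady),
                 theta_depl = as.numeric(theta_depl),
                 theta_oe = as.numeric(theta_oe),
                 theta_wt_decay_gate = as.numeric(theta_wt_decay_gate),
                 theta_stab = as.numeric(theta_stab),
                 min_criteria = as.integer(min_criteria),
                 stab_mode = stab_mode)
}

#' Venn accounting of the four criterion sets
#'
#' Exclusive region counts for the 15 non-empty subsets of the four
#' criterion sets (steady, depl, oe, stab), the tallies of proteins meeting
#' exactly 4, 3, 2 or 1 criteria, and the count meeting none.
#'
#' @slot regions named integer vector of length 15; names are sorted
#'   criterion labels joined by `+` (e.g. `"steady+stab"`). Each count is
#'   exclusive: proteins in exactly that combination of sets.
#' @slot by_k named integer vector with names `"4","3","2","1"`.
#' @slot n_zero integer, proteins satisfying no criterion.
#' @aliases VennCounts-class
#' @seealso [vennCounts()]
#' @exportClass VennCounts
setClass("VennCounts",
         representation(regions = "integer",
                        by_k = "integer",
                        n_zero = "integer"))

setValidity("VennCounts", function(object) {
    if (length(object@regions) != 15L)
        return("regions must have 15 entries")
    if (!identical(names(object@by_k), c("4", "3", "2", "1")))
        return("by_k must be named '4','3','2','1'")
    card <- lengths(strsplit(names(object@regions), "+", fixed = TRUE))
    for (k in 1:4) {
        if (sum(object@regions[card == k]) != object@by_k[as.character(k)])
            return("by_k must equal sums of exclusive regions by cardinality")
    }
    if (any(c(object@regions, object@by_k, object@n_zero) < 0))
        return("counts must be non-negative")
    TRUE
})

#' Half-life estimate from a translation shut-off chase
#'
#' Result of a log-linear fit of relative protein level against time. A
#' non-positive decay constant (no net decay, or apparent accumulation) is
#' reported as "stable": `t_half` is `Inf` and [isStable()] is `TRUE`.
#'
#' @slot k decay constant, per minute.
#' @slot t_half half-life in minutes, `log(2)/k`; `Inf` when `k <= 0`.
#' @slot r_squared coefficient of determination of the log-linear fit
#'   (`NA` for a 2-point fit through which the line is exact).
#' @slot n_points number of time points used.
#' @aliases HalfLifeEstimate-class
#' @seealso [fitHalfLife()]
#' @exportClass HalfLifeEstimate
setClass("HalfLifeEstimate",
         representation(k = "numeric",
                        t_half = "numeric",
                        r_squared = "numeric",
                        n_points = "integer"))

setValidity("HalfLifeEstimate", function(object) {
    if (length(object@k) != 1L || !is.finite(object@k))
        return("k must be a single finite number")
    if (is.finite(object@t_half) &&
        abs(object@t_half * object@k - log(2)) > 1e-8 * log(2))
        return("t_half * k must equal log(2) when t_half is finite")
    if (object@n_points < 2L)
        return("at least two points are required")
    TRUE
})
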