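## Operating characteristics of the screen on data with planted truth:
## confusion-matrix recovery metrics and threshold sweeps. Proteins the
## screen never saw (dropped in every replicate) are excluded from the
## metrics -- sensitivity stays interpretable as the recoverable fraction
## -- and their count is reported separately.

#' Score screen output against planted truth
#'
#' Positive = the candidate table's `putative` call; condition-positive =
#' planted class `lon_substrate`. Candidates must all appear in the truth
#' table; truth proteins absent from the candidate table are counted as
#' undetected and excluded.
#'
#' @param candidates candidate table from [selectCandidates()].
#' @param truth truth data frame from [simulateScreenData()] (columns
#'   `protein_id`, `class`).
#' @return Named list: integer `tp`, `fp`, `tn`, `fn`, `n_undetected`;
#'   `sensitivity`, `specificity`, `precision`, `fdp` in [0, 1] with `NA`
#'   where the denominator is 0.
#' @examples
#' sim <- simulateScreenData(simulationParams(n_substrates = 10,
#'                                            n_stable_nonsubstrates = 90,
#'                                            n_nonlon_unstable = 0,
#'                                            noise_sigma = 0,
#'                                            dropout_p = 0),
#'                           seed = 2)
#' res <- screenSubstrates(sim$experiment)
#' scoreRecovery(res$candidates, sim$truth)$sensitivity
#' @export
scoreRecovery <- function(candidates, truth) {
    missing <- setdiff(candidates$protein_id, truth$protein_id)
    if (length(missing))
        stop("candidate protein(s) missing from truth: ",
             paste(utils::head(missing, 5), collapse = ", "))
    cls <- truth$class[match(candidates$protein_id, truth$protein_id)]
    pos <- candidates$putative
    is_sub <- cls == "lon_substrate"
    tp <- sum(pos & is_sub)
    fp <- sum(pos & !is_sub)
    fn <- sum(!pos & is_sub)
    tn <- sum(!pos & !is_sub)
    frac <- function(num, den) if (den > 0) num / den else NA_real_
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         n_undetected = nrow(truth) - nrow(candidates),
         sensitivity = frac(tp, tp + fn),
         specificity = frac(tn, tn + fp),
         precision = frac(tp, tp + fp),
         fdp = frac(fp, tp + fp))
}

#' Sweep thresholds and score each grid point
#'
#' Reruns the screen on one fixed abundance experiment for every row of a
#' threshold grid and scores each result against the planted truth. The
#' sweep is deterministic given the experiment. Raising `min_criteria`
#' never increases sensitivity and never decreases specificity.
#'
#' @param x a [LonScreenExperiment-class].
#' @param truth truth data frame (see [scoreRecovery()]).
#' @param grid data frame whose columns are any subset of the
#'   [criteriaThresholds()] arguments; one screen run per row. Unlisted
#'   parameters keep their defaults.
#' @return `grid` with the [scoreRecovery()] metrics appended as columns.
#' @examples
#' sim <- simulateScreenData(simulationParams(n_substrates = 10,
#'                                            n_stable_nonsubstrates = 40,
#'                                            n_nonlon_unstable = 5),
#'                           seed = 3)
#' thresholdSweep(sim$experiment, sim$truth,
#'                data.frame(min_criteria = 1:4))
#' @export
thresholdSweep <- function(x, truth, grid) {
    if (!is.data.frame(grid) || nrow(grid) < 1L)
        stop("'grid' must be a non-empty data frame")
    ok <- names(formals(criteriaThresholds))
    bad <- setdiff(colnames(grid), ok)
    if (length(bad))
        stop("unknown threshold parameter(s): ", paste(bad, collapse = ", "))
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        th <- do.call(criteriaThresholds,
                      as.list(grid[i, , drop = FALSE]))
        res <- screenSubstrates(x, thresholds = th)
        as.data.frame(scoreRecovery(res$candidates, truth))
    })
    cbind(grid, do.call(rbind, rows), row.names = NULL)
}
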