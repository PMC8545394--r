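## The four-criterion ratio screen. Per replicate, five condition ratios
## are formed from the ten channels; ratios are averaged over replicates
## (falling back to the single value for proteins detected in only one
## replicate), thresholded, and combined by a >= k-of-4 rule. No
## significance testing is involved: the screen is a deterministic
## threshold filter, by design.

.ratioDefs <- list(
    r_steady = c("DLON_T0", "WT_T0"),
    r_depl = c("DEPL_NO_VAN", "DEPL_PLUS_VAN"),
    r_oe = c("OE_GLUC", "OE_XYL1H"),
    r_wt_decay = c("WT_T0", "WT_T30"),
    r_dlon_decay = c("DLON_T0", "DLON_T30"))

.criterionLabels <- c(c_steady = "steady", c_depl = "depl",
                      c_oe = "oe", c_stab = "stab")

#' Per-replicate condition ratios
#'
#' For every protein and replicate, computes the five screen ratios:
#' \describe{
#'   \item{r_steady}{`DLON_T0 / WT_T0` -- steady-state level without Lon
#'     relative to wild type.}
#'   \item{r_depl}{`DEPL_NO_VAN / DEPL_PLUS_VAN` -- level after Lon
#'     depletion relative to Lon-expressing conditions.}
#'   \item{r_oe}{`OE_GLUC / OE_XYL1H` -- level before relative to after
#'     1 h of induced \emph{lon} overexpression.}
#'   \item{r_wt_decay}{`WT_T0 / WT_T30` -- loss over 30 min of translation
#'     shut-off in the wild type.}
#'   \item{r_dlon_decay}{`DLON_T0 / DLON_T30` -- the same without Lon.}
#' }
#' A ratio is present iff both of its channels were measured for that
#' protein/replicate; missingness propagates silently as `NA`. Ratios are
#' invariant to rescaling all channels of a protein within a replicate.
#'
#' @param x a [LonScreenExperiment-class].
#' @return A 3-d numeric array `proteins x replicates x 5 ratios` with
#'   dimnames, `NA` where a needed channel is missing.
#' @seealso [aggregateReplicates()]
#' @export
computeRatios <- function(x) {
    stopifnot(methods::is(x, "LonScreenExperiment"))
    a <- abundances(x)
    reps <- replicates(x)
    out <- array(NA_real_,
                 dim = c(nrow(a), length(reps), length(.ratioDefs)),
                 dimnames = list(rownames(a), reps, names(.ratioDefs)))
    for (r in reps) {
        for (nm in names(.ratioDefs)) {
            num <- a[, paste(r, .ratioDefs[[nm]][1], sep = ":")]
            den <- a[, paste(r, .ratioDefs[[nm]][2], sep = ":")]
            out[, r, nm] <- num / den
        }
    }
    out
}

#' Replicate-averaged ratios with single-replicate fallback
#'
#' Averages each per-replicate ratio arithmetically over the replicates in
#' which it is present. For proteins detected in only one replicate the
#' single value is used as-is (provenance `"single_replicate"`); with no
#' present value the mean is `NA` (provenance `"missing"`). The
#' stabilization ratio (wild-type decay over no-Lon decay) is then derived:
#' with `stab_mode = "from_means"` (default) as the quotient of the
#' averaged decay ratios, with `"per_replicate_mean"` as the average of the
#' per-replicate ratios-of-ratios.
#'
#' @param ratios array from [computeRatios()].
#' @param stab_mode see [CriteriaThresholds-class].
#' @return A data frame, one row per protein: `protein_id`, the five mean
#'   ratios, `r_stabilization`, and a provenance column `prov_<ratio>` per
#'   ratio with values `both_replicates` / `single_replicate` / `missing`
#'   (`both_replicates` meaning >= 2 replicates contributed).
#' @export
aggregateReplicates <- function(ratios,
                                stab_mode = c("from_means",
                                              "per_replicate_mean")) {
    stab_mode <- match.arg(stab_mode)
    stopifnot(is.array(ratios), length(dim(ratios)) == 3L)
    rn <- dimnames(ratios)[[3]]
    out <- data.frame(protein_id = dimnames(ratios)[[1]],
                      stringsAsFactors = FALSE)
    for (nm in rn) {
        v <- ratios[, , nm, drop = FALSE]
        dim(v) <- dim(ratios)[1:2]
        n <- rowSums(!is.na(v))
        m <- rowMeans(v, na.rm = TRUE)
        m[n == 0] <- NA_real_
        out[[nm]] <- m
        out[[paste0("prov_", nm)]] <-
            c("missing", "single_replicate",
              "both_replicates")[pmin(n, 2L) + 1L]
    }
    if (stab_mode == "from_means") {
        out$r_stabilization <- out$r_wt_decay / out$r_dlon_decay
    } else {
        rr <- ratios[, , "r_wt_decay", drop = FALSE] /
            ratios[, , "r_dlon_decay", drop = FALSE]
        dim(rr) <- dim(ratios)[1:2]
        n <- rowSums(!is.na(rr))
        m <- rowMeans(rr, na.rm = TRUE)
        m[n == 0] <- NA_real_
        out$r_stabilization <- m
    }
    out$prov_r_stabilization <-
        ifelse(is.na(out$r_stabilization), "missing",
               ifelse(out$prov_r_wt_decay == "single_replicate" |
                      out$prov_r_dlon_decay == "single_replicate",
                      "single_replicate", "both_replicates"))
    rownames(out) <- NULL
    out
}

#' Apply the four substrate criteria
#'
#' Thresholds the replicate-averaged ratios into the four criterion flags.
#' All comparisons are inclusive (`>=`):
#' `c_steady = r_steady >= theta_steady`; `c_depl = r_depl >= theta_depl`;
#' `c_oe = r_oe >= theta_oe`; and the two-stage stabilization criterion
#' `c_stab = (r_wt_decay >= theta_wt_decay_gate) & (r_stabilization >=
#' theta_stab)` -- a protein must first show net decay in the wild type
#' before stabilization without Lon is assessed. A missing mean ratio makes
#' its criterion `FALSE` (the protein can still qualify via the other
#' three, as single-replicate proteins were scored in the original screen).
#'
#' @param means data frame from [aggregateReplicates()].
#' @param thresholds a [CriteriaThresholds-class].
#' @return A data frame: `protein_id`, logical `c_steady`, `c_depl`,
#'   `c_oe`, `c_stab`, integer `n_criteria`.
#' @export
applyCriteria <- function(means, thresholds = criteriaThresholds()) {
    stopifnot(methods::is(thresholds, "CriteriaThresholds"))
    ge <- function(v, th) !is.na(v) & v >= th
    out <- data.frame(protein_id = means$protein_id,
                      c_steady = ge(means$r_steady, thresholds@theta_steady),
                      c_depl = ge(means$r_depl, thresholds@theta_depl),
                      c_oe = ge(means$r_oe, thresholds@theta_oe),
                      c_stab = ge(means$r_wt_decay,
                                  thresholds@theta_wt_decay_gate) &
                          ge(means$r_stabilization, thresholds@theta_stab),
                      stringsAsFactors = FALSE)
    out$n_criteria <- as.integer(out$c_steady + out$c_depl +
                                 out$c_oe + out$c_stab)
    out
}

#' Assemble the candidate table
#'
#' Combines mean ratios and criterion flags into the screen's result
#' table, calling a protein a putative substrate when it meets at least
#' `min_criteria` of the four criteria. Every detected protein appears in
#' the table; non-candidates carry `putative = FALSE`.
#'
#' @param means data frame from [aggregateReplicates()].
#' @param flags data frame from [applyCriteria()] (computed from `means`
#'   and `thresholds` if omitted).
#' @param thresholds a [CriteriaThresholds-class].
#' @param category_map optional named character vector from
#'   [readCategoryMap()]; unmapped proteins get `"unclassified"`.
#' @return The candidate table data frame with the fixed column order
#'   documented in [writeCandidates()].
#' @export
selectCandidates <- function(means, flags = NULL,
                             thresholds = criteriaThresholds(),
                             category_map = NULL) {
    if (is.null(flags))
        flags <- applyCriteria(means, thresholds)
    stopifnot(identical(means$protein_id, flags$protein_id))
    out <- data.frame(protein_id = means$protein_id,
                      r_steady = means$r_steady,
                      r_depl = means$r_depl,
                      r_oe = means$r_oe,
                      r_wt_decay = means$r_wt_decay,
                      r_stabilization = means$r_stabilization,
                      c_steady = flags$c_steady,
                      c_depl = flags$c_depl,
                      c_oe = flags$c_oe,
                      c_stab = flags$c_stab,
                      n_criteria = flags$n_criteria,
                      putative = flags$n_criteria >= thresholds@min_criteria,
                      stringsAsFactors = FALSE)
    out$category <- if (is.null(category_map)) NA_character_ else {
        cat <- unname(category_map[out$protein_id])
        ifelse(is.na(cat), "unclassified", cat)
    }
    out
}

#' Venn accounting of the criterion sets
#'
#' Counts, for every non-empty subset of the four criterion sets, the
#' proteins lying in exactly that combination (exclusive regions of the
#' 4-set Venn diagram), plus the tallies of proteins meeting exactly
#' 4, 3, 2 or 1 criteria and the count meeting none.
#'
#' @param flags data frame from [applyCriteria()].
#' @return A [VennCounts-class] object.
#' @export
vennCounts <- function(flags) {
    fm <- as.matrix(flags[, names(.criterionLabels)])
    subsets <- unlist(lapply(1:4, function(k)
        utils::combn(unname(.criterionLabels), k,
                     paste, collapse = "+", simplify = FALSE)),
        use.names = FALSE)
    pattern <- apply(fm, 1L, function(row)
        paste(.criterionLabels[names(.criterionLabels)[row]],
              collapse = "+"))
    regions <- stats::setNames(integer(length(subsets)), subsets)
    tab <- table(pattern[pattern != ""])
    regions[names(tab)] <- as.integer(tab)
    nk <- rowSums(fm)
    by_k <- stats::setNames(vapply(4:1, function(k) sum(nk == k), 0L),
                            as.character(4:1))
    methods::new("VennCounts", regions = regions, by_k = by_k,
                 n_zero = sum(nk == 0L))
}

#' Run the whole screen on an abundance experiment
#'
#' Convenience wrapper chaining [computeRatios()], [aggregateReplicates()],
#' [applyCriteria()], [selectCandidates()] and [vennCounts()].
#'
#' @param x a [LonScreenExperiment-class].
#' @param thresholds a [CriteriaThresholds-class].
#' @param category_map optional named character vector.
#' @return List with elements `means`, `flags`, `candidates` (the
#'   candidate table) and `venn` (a [VennCounts-class]).
#' @examples
#' sim <- simulateScreenData(simulationParams(n_substrates = 10,
#'                                            n_stable_nonsubstrates = 40,
#'                                            n_nonlon_unstable = 5,
#'                                            noise_sigma = 0),
#'                           seed = 7)
#' res <- screenSubstrates(sim$experiment)
#' sum(res$candidates$putative)
#' res$venn
#' @export
screenSubstrates <- function(x, thresholds = criteriaThresholds(),
                             category_map = NULL) {
    ratios <- computeRatios(x)
    means <- aggregateReplicates(ratios, stab_mode = thresholds@stab_mode)
    detected <- detectedProteins(x)
    means <- means[means$protein_id %in% detected, , drop = FALSE]
    flags <- applyCriteria(means, thresholds)
    candidates <- selectCandidates(means, flags, thresholds, category_map)
    list(means = means, flags = flags, candidates = candidates,
         venn = vennCounts(flags))
}
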