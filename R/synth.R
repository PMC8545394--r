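## Synthetic two-replicate, ten-channel abundance matrices with planted
## ground truth. Three protein classes are planted:
##   lon_substrate       - elevated without Lon (f_steady), up on depletion
##                         (f_depl), down on overexpression (f_oe < 1 on
##                         the gluc/+xyl denominator side), degraded in the
##                         wild type (k_wt) but not without Lon (k_dlon).
##   stable_nonsubstrate - flat across all channels.
##   nonlon_unstable     - degraded at k_nonlon in BOTH backgrounds, all
##                         other channels flat: a Lon-independent turnover
##                         control that must not be called.
## Channel values get multiplicative lognormal noise (median 1) and whole
## (protein, replicate) pairs drop out with probability dropout_p, which
## reproduces proteins detected in only one replicate.

#' Parameters of the synthetic screen data generator
#'
#' Defaults state the conditions the screen's evaluation assumes: 100
#' planted substrates among 1100 proteins, a 1.5-fold steady-state and
#' depletion effect, a 1.5-fold overexpression effect (`f_oe = 0.67` on
#' the `OE_XYL1H` channel, so the gluc/+xyl ratio is about 1.5), wild-type
#' turnover at a 12-minute half-life (`k_wt = log(2)/12` per min) with
#' complete stabilization without Lon (`k_dlon = 0`), a Lon-independent
#' unstable class decaying at the same rate in both backgrounds, 10%
#' lognormal channel noise and 5% whole-replicate dropout. The base
#' abundance is log-uniform over `base_range`.
#'
#' @param n_substrates,n_stable_nonsubstrates,n_nonlon_unstable class
#'   sizes (non-negative integers).
#' @param f_steady,f_depl planted fold effects for substrates (> 0).
#' @param f_oe multiplier on the `OE_XYL1H` channel for substrates; must be
#'   in (0, 1] so that overexpressing the protease lowers substrate levels.
#' @param k_wt,k_dlon,k_nonlon decay constants, per minute (>= 0).
#' @param noise_sigma SD of the multiplicative lognormal noise on the
#'   natural-log scale (>= 0).
#' @param dropout_p probability that a protein is undetected in a given
#'   replicate, in [0, 1); `per_channel_dropout = TRUE` applies it per
#'   channel instead.
#' @param base_range range of the log-uniform base abundance draw
#'   (arbitrary reporter-intensity units).
#' @param times chase time points in minutes; must start at 0 and include
#'   the 0/15/30 grid channels expect (fixed at length 3).
#' @param n_replicates number of biological replicates (>= 1).
#' @param per_channel_dropout logical.
#' @return A validated list of class `"SimulationParams"`.
#' @seealso [simulateScreenData()]
#' @export
simulationParams <- function(n_substrates = 100L,
                             n_stable_nonsubstrates = 900L,
                             n_nonlon_unstable = 100L,
                             f_steady = 1.5,
                             f_depl = 1.5,
                             f_oe = 0.67,
                             k_wt = log(2) / 12,
                             k_dlon = 0,
                             k_nonlon = log(2) / 12,
                             noise_sigma = 0.1,
                             dropout_p = 0.05,
                             base_range = c(1e4, 1e7),
                             times = c(0, 15, 30),
                             n_replicates = 2L,
                             per_channel_dropout = FALSE) {
    p <- list(n_substrates = as.integer(n_substrates),
              n_stable_nonsubstrates = as.integer(n_stable_nonsubstrates),
              n_nonlon_unstable = as.integer(n_nonlon_unstable),
              f_steady = f_steady, f_depl = f_depl, f_oe = f_oe,
              k_wt = k_wt, k_dlon = k_dlon, k_nonlon = k_nonlon,
              noise_sigma = noise_sigma, dropout_p = dropout_p,
              base_range = as.numeric(base_range), times = as.numeric(times),
              n_replicates = as.integer(n_replicates),
              per_channel_dropout = isTRUE(per_channel_dropout))
    counts <- c(p$n_substrates, p$n_stable_nonsubstrates, p$n_nonlon_unstable)
    if (any(is.na(counts)) || any(counts < 0L))
        stop("class counts must be non-negative integers")
    if (sum(counts) < 1L)
        stop("at least one protein must be simulated")
    if (!(p$f_steady > 0) || !(p$f_depl > 0))
        stop("f_steady and f_depl must be > 0")
    if (!(p$f_oe > 0) || p$f_oe > 1)
        stop("f_oe must be in (0, 1]")
    if (any(c(p$k_wt, p$k_dlon, p$k_nonlon) < 0))
        stop("decay constants must be >= 0")
    if (p$noise_sigma < 0)
        stop("noise_sigma must be >= 0")
    if (p$dropout_p < 0 || p$dropout_p >= 1)
        stop("dropout_p must be in [0, 1)")
    if (length(p$base_range) != 2L || any(p$base_range <= 0) ||
        diff(p$base_range) < 0)
        stop("base_range must be an increasing positive pair")
    if (length(p$times) != 3L || p$times[1] != 0 ||
        any(diff(p$times) <= 0))
        stop("times must be three strictly increasing values starting at 0")
    if (p$n_replicates < 1L)
        stop("n_replicates must be >= 1")
    structure(p, class = "SimulationParams")
}

## noiseless channel means for one protein given its planted parameters
.channelMeans <- function(B, class, p) {
    tt <- p$times
    m <- stats::setNames(rep(B, 10L), lonChannels())
    if (class == "lon_substrate") {
        m[c("WT_T0", "WT_T15", "WT_T30")] <- B * exp(-p$k_wt * tt)
        m[c("DLON_T0", "DLON_T15", "DLON_T30")] <-
            p$f_steady * B * exp(-p$k_dlon * tt)
        m["DEPL_NO_VAN"] <- p$f_depl * B
        m["DEPL_PLUS_VAN"] <- B
        m["OE_GLUC"] <- B
        m["OE_XYL1H"] <- p$f_oe * B
    } else if (class == "nonlon_unstable") {
        m[c("WT_T0", "WT_T15", "WT_T30")] <- B * exp(-p$k_nonlon * tt)
        m[c("DLON_T0", "DLON_T15", "DLON_T30")] <- B * exp(-p$k_nonlon * tt)
    }
    m
}

#' Simulate a screen dataset with planted ground truth
#'
#' Draws a log-uniform base abundance per protein, sets the noiseless
#' channel means according to the protein's planted class (see
#' [simulationParams()]), multiplies every channel value by independent
#' median-1 lognormal noise, and drops whole (protein, replicate) pairs
#' with probability `dropout_p`. Identical `params` and `seed` give
#' bit-identical output.
#'
#' @param params a `SimulationParams` list from [simulationParams()].
#' @param seed integer seed; all randomness is derived from it.
#' @return List with `experiment` (a [LonScreenExperiment-class]) and
#'   `truth`, a data frame with one row per simulated protein:
#'   `protein_id`, `class`, and the planted per-protein parameters
#'   (`base`, `f_steady`, `f_depl`, `f_oe`, `k_wt`, `k_dlon`).
#' @examples
#' sim <- simulateScreenData(simulationParams(n_substrates = 3,
#'                                            n_stable_nonsubstrates = 3,
#'                                            n_nonlon_unstable = 0,
#'                                            noise_sigma = 0,
#'                                            dropout_p = 0),
#'                           seed = 1)
#' sim$truth$class
#' @export
simulateScreenData <- function(params = simulationParams(), seed = 1L) {
    if (!inherits(params, "SimulationParams"))
        params <- do.call(simulationParams, params)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))

    classes <- rep(c("lon_substrate", "stable_nonsubstrate",
                     "nonlon_unstable"),
                   times = c(params$n_substrates,
                             params$n_stable_nonsubstrates,
                             params$n_nonlon_unstable))
    n <- length(classes)
    ids <- sprintf("SYN_%04d", seq_len(n))
    base <- exp(stats::runif(n, log(params$base_range[1]),
                             log(params$base_range[2])))

    reps <- paste0("rep", seq_len(params$n_replicates))
    mat <- matrix(NA_real_, nrow = n, ncol = length(reps) * 10L,
                  dimnames = list(ids,
                                  paste(rep(reps, each = 10L),
                                        rep(lonChannels(), length(reps)),
                                        sep = ":")))
    for (i in seq_len(n)) {
        mu <- .channelMeans(base[i], classes[i], params)
        for (r in reps) {
            noise <- if (params$noise_sigma > 0)
                stats::rlnorm(10L, meanlog = 0, sdlog = params$noise_sigma)
            else rep(1, 10L)
            mat[i, paste(r, lonChannels(), sep = ":")] <- mu * noise
        }
    }
    ## dropout after value generation so the draw count (hence the values
    ## of everything else) does not depend on dropout_p
    if (params$dropout_p > 0) {
        if (params$per_channel_dropout) {
            drop <- matrix(stats::runif(length(mat)) < params$dropout_p,
                           nrow = nrow(mat))
            mat[drop] <- NA_real_
        } else {
            for (r in reps) {
                drop <- stats::runif(n) < params$dropout_p
                mat[drop, paste(r, lonChannels(), sep = ":")] <- NA_real_
            }
        }
    }
    truth <- data.frame(protein_id = ids,
                        class = classes,
                        base = base,
                        f_steady = ifelse(classes == "lon_substrate",
                                          params$f_steady, 1),
                        f_depl = ifelse(classes == "lon_substrate",
                                        params$f_depl, 1),
                        f_oe = ifelse(classes == "lon_substrate",
                                      params$f_oe, 1),
                        k_wt = ifelse(classes == "lon_substrate",
                                      params$k_wt,
                                      ifelse(classes == "nonlon_unstable",
                                             params$k_nonlon, 0)),
                        k_dlon = ifelse(classes == "lon_substrate",
                                        params$k_dlon,
                                        ifelse(classes == "nonlon_unstable",
                                               params$k_nonlon, 0)),
                        stringsAsFactors = FALSE)
    list(experiment = LonScreenExperiment(
             mat,
             replicate = rep(reps, each = 10L),
             channel = rep(lonChannels(), length(reps))),
         truth = truth)
}

#' Write a simulated dataset as a rerunnable fixture
#'
#' Emits three plain-text files into `out_dir`: `abundance.tsv` (wide
#' dialect, re-readable with [readAbundanceTable()]), `truth.tsv` and
#' `params.txt` (flat `key = value` lines including the seed), enough to
#' rerun the screen end to end.
#'
#' @param params a `SimulationParams`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed passed to [simulateScreenData()].
#' @return Invisibly, the named character vector of file paths.
#' @export
writeFixture <- function(params = simulationParams(), out_dir, seed = 1L) {
    if (!dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)
    sim <- simulateScreenData(params, seed = seed)
    paths <- c(abundance = file.path(out_dir, "abundance.tsv"),
               truth = file.path(out_dir, "truth.tsv"),
               params = file.path(out_dir, "params.txt"))
    writeAbundanceTable(sim$experiment, paths["abundance"], dialect = "wide")
    write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    kv <- c(lapply(unclass(params),
                   function(v) paste(format(v, digits = 15),
                                     collapse = ",")),
            list(seed = as.integer(seed)))
    writeLines(paste(names(kv), unlist(kv), sep = " = "), paths["params"])
    invisible(paths)
}
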