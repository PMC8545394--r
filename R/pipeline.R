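## End-to-end entry point: read (or simulate) the abundance table, run the
## screen, optionally tally categories, and emit the candidate table, the
## Venn counts and a machine-readable run report whose every number can be
## recomputed from the emitted artifacts.

.readConfigFile <- function(path) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
    if (any(lengths(kv) != 3L))
        stop("config lines must be 'key = value'")
    vals <- lapply(kv, function(m) {
        v <- trimws(m[3])
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num)) num
        else if (v %in% c("TRUE", "FALSE")) as.logical(v)
        else v
    })
    stats::setNames(vals, vapply(kv, function(m) trimws(m[2]), ""))
}

#' Run the screen pipeline end to end
#'
#' Reads an abundance table (or simulates one first), runs the
#' four-criterion screen, optionally tallies functional categories, and
#' writes three artifacts into `out_dir`: `candidates.tsv` (the candidate
#' table), `venn.json` (exclusive region counts, by-k tallies and the
#' zero-criteria count) and `report.json` (input digest, thresholds used,
#' headline counts, warnings, package version and seed). The run is
#' deterministic given inputs and seed; on any stage failure partial
#' outputs are removed and the error is rethrown with the stage name.
#'
#' @param config a named list, or the path of a flat `key = value` file.
#'   Recognized keys: `abundance` (TSV path) with `dialect`
#'   (`wide`/`long`); or `simulate = TRUE` with `seed` and any
#'   [simulationParams()] argument; `category_map` (TSV path, optional);
#'   any [criteriaThresholds()] argument (defaults reproduce the published
#'   procedure); `out_dir` (default `"."`).
#' @return Invisibly, a list with `candidates`, `venn`, `report` and the
#'   file `paths`.
#' @examples
#' out <- runPipeline(list(simulate = TRUE, seed = 11,
#'                         n_substrates = 5, n_stable_nonsubstrates = 20,
#'                         n_nonlon_unstable = 0,
#'                         out_dir = tempfile("run")))
#' out$report$putative_count
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- .readConfigFile(config)
    stopifnot(is.list(config))
    out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
    if (!dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)
    paths <- c(candidates = file.path(out_dir, "candidates.tsv"),
               venn = file.path(out_dir, "venn.json"),
               report = file.path(out_dir, "report.json"))
    written <- character()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            unlink(written)
            stop("pipeline stage '", name, "': ", conditionMessage(e),
                 call. = FALSE)
        })
    }

    seed <- if (is.null(config$seed)) NA_integer_ else as.integer(config$seed)
    input <- stage("input", {
        if (isTRUE(config$simulate)) {
            sp_args <- config[intersect(names(config),
                                        names(formals(simulationParams)))]
            sim <- simulateScreenData(do.call(simulationParams, sp_args),
                                      seed = if (is.na(seed)) 1L else seed)
            list(x = sim$experiment, source = "simulated")
        } else if (!is.null(config$abundance)) {
            dialect <- if (is.null(config$dialect)) "wide" else config$dialect
            list(x = readAbundanceTable(config$abundance, dialect = dialect),
                 source = config$abundance)
        } else stop("config must name an 'abundance' table or set simulate = TRUE")
    })
    x <- input$x

    category_map <- stage("category_map",
        if (is.null(config$category_map)) NULL
        else readCategoryMap(config$category_map))

    thresholds <- stage("thresholds", {
        th_args <- config[intersect(names(config),
                                    names(formals(criteriaThresholds)))]
        do.call(criteriaThresholds, th_args)
    })

    res <- stage("screen", screenSubstrates(x, thresholds, category_map))

    stage("write", {
        writeCandidates(res$candidates, paths["candidates"])
        written <<- paths["candidates"]
        venn_obj <- list(regions = as.list(vennRegions(res$venn)),
                         by_k = as.list(vennByK(res$venn)),
                         n_zero = vennZero(res$venn))
        jsonlite::write_json(venn_obj, paths["venn"], auto_unbox = TRUE)
        written <<- c(written, paths["venn"])
    })

    report <- stage("report", {
        mask <- detectionMask(x)
        ratio_cols <- paste0("prov_", c(ratioNames(), "r_stabilization"))
        single_rep <- sum(vapply(ratio_cols, function(cc)
            sum(res$means[[cc]] == "single_replicate"), 0L))
        missing_ratio <- sum(vapply(ratio_cols, function(cc)
            sum(res$means[[cc]] == "missing"), 0L))
        by_k <- vennByK(res$venn)
        putative_count <- sum(res$candidates$putative)
        keep <- as.character(seq(4L, thresholds@min_criteria))
        stopifnot(sum(by_k[keep]) == putative_count)  # internal cross-check
        rep <- list(
            input = list(source = input$source,
                         n_proteins = nrow(x),
                         detected_per_replicate = as.list(
                             stats::setNames(colSums(mask), colnames(mask))),
                         detected_union = length(detectedProteins(x))),
            thresholds = list(theta_steady = thresholds@theta_steady,
                              theta_depl = thresholds@theta_depl,
                              theta_oe = thresholds@theta_oe,
                              theta_wt_decay_gate = thresholds@theta_wt_decay_gate,
                              theta_stab = thresholds@theta_stab,
                              min_criteria = thresholds@min_criteria,
                              stab_mode = thresholds@stab_mode),
            by_k = as.list(by_k),
            putative_count = putative_count,
            category_tally = if (is.null(category_map)) NULL else
                tallyCategories(
                    res$candidates$protein_id[res$candidates$putative],
                    category_map),
            warnings = list(single_replicate_ratios = single_rep,
                            missing_mean_ratios = missing_ratio),
            version = as.character(utils::packageVersion("lonscreen")),
            seed = seed)
        jsonlite::write_json(rep, paths["report"], auto_unbox = TRUE,
                             digits = NA, null = "null")
        written <- c(written, paths["report"])
        rep
    })

    invisible(list(candidates = res$candidates, venn = res$venn,
                   report = report, paths = paths))
}
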