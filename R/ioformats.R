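## Tab-separated I/O for the screen's three tables: the abundance matrix
## (wide or long dialect), the candidate table and the protein -> functional
## category map. All files are UTF-8 TSV with a mandatory header and '.'
## decimal. On read, empty cells, "NA" and "0" all mean "not measured":
## every downstream quantity is a ratio, so a zero intensity is treated as
## missingness, never as an abundance.

.candidateColumns <- c("protein_id",
                       "r_steady", "r_depl", "r_oe", "r_wt_decay",
                       "r_stabilization",
                       "c_steady", "c_depl", "c_oe", "c_stab",
                       "n_criteria", "putative", "category")

.parseAbundanceCell <- function(x, rows, what) {
    x <- trimws(x)
    missing <- is.na(x) | x == "" | x == "NA" | x == "0"
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!missing & is.na(out))
    if (length(bad))
        stop("non-numeric abundance '", x[bad[1]], "' in ", what,
             ", row ", rows[bad[1]])
    neg <- which(!missing & out <= 0)
    if (length(neg))
        stop("non-positive abundance in ", what, ", row ", rows[neg[1]],
             " (zeros must be encoded as missing)")
    out[missing] <- NA_real_
    out
}

#' Read a protein abundance table
#'
#' Reads the screen's quantitative input: positive reporter intensities per
#' protein for every replicate/channel combination. Two dialects are
#' supported. The canonical \emph{wide} dialect has a `protein_id` column
#' followed by one column per sample named `<replicate>:<channel>` (e.g.
#' `rep1:WT_T0`), twenty value columns for the standard two-replicate
#' design. The \emph{long} dialect has columns `protein_id`, `replicate`,
#' `channel`, `abundance`, one measured cell per row.
#'
#' Empty cells, `"NA"` and `"0"` are all read as missing, never as a zero
#' abundance. A protein counts as detected in a replicate if it has at
#' least one measured channel there.
#'
#' @param path path to a TSV file.
#' @param dialect `"wide"` (default) or `"long"`.
#' @return A [LonScreenExperiment-class].
#' @seealso [writeAbundanceTable()], [LonScreenExperiment()]
#' @export
readAbundanceTable <- function(path, dialect = c("wide", "long")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("abundance table not found: ", path)
    raw <- read.delim(path, sep = "\t", colClasses = "character",
                      check.names = FALSE, na.strings = NULL,
                      fileEncoding = "UTF-8")
    if (dialect == "wide")
        .readWide(raw, path)
    else
        .readLong(raw, path)
}

.readWide <- function(raw, path) {
    if (ncol(raw) < 1L || colnames(raw)[1] != "protein_id")
        stop("wide abundance table must start with a 'protein_id' column: ",
             path)
    ids <- raw[[1]]
    if (anyDuplicated(ids))
        stop("duplicate protein identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    valcols <- colnames(raw)[-1]
    parts <- strsplit(valcols, ":", fixed = TRUE)
    ok <- lengths(parts) == 2L
    chan <- vapply(parts, function(p) p[length(p)], "")
    if (any(!ok) || !all(chan %in% lonChannels())) {
        offending <- valcols[!ok | !chan %in% lonChannels()][1]
        stop("column '", offending, "' is not '<replicate>:<channel>' with ",
             "a known channel label")
    }
    rep <- vapply(parts, `[`, "", 1L)
    reps <- unique(rep)
    # complete grid; columns absent from the file stay all-missing
    mat <- matrix(NA_real_, nrow = nrow(raw),
                  ncol = length(reps) * length(lonChannels()),
                  dimnames = list(ids, paste(rep(reps, each = 10),
                                             rep(lonChannels(), length(reps)),
                                             sep = ":")))
    for (j in seq_along(valcols)) {
        key <- paste(rep[j], chan[j], sep = ":")
        mat[, key] <- .parseAbundanceCell(raw[[j + 1L]],
                                          rows = seq_len(nrow(raw)) + 1L,
                                          what = paste0("column '",
                                                        valcols[j], "'"))
    }
    LonScreenExperiment(mat,
                        replicate = rep(reps, each = 10),
                        channel = rep(lonChannels(), length(reps)))
}

.readLong <- function(raw, path) {
    need <- c("protein_id", "replicate", "channel", "abundance")
    if (!all(need %in% colnames(raw)))
        stop("long abundance table must have columns ",
             paste(need, collapse = ", "), ": ", path)
    bad <- setdiff(unique(raw$channel), lonChannels())
    if (length(bad))
        stop("column 'channel' contains unknown channel label(s): ",
             paste(bad, collapse = ", "))
    key <- paste(raw$protein_id, raw$replicate, raw$channel, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (protein, replicate, channel) row(s) in ", path)
    vals <- .parseAbundanceCell(raw$abundance,
                                rows = seq_len(nrow(raw)) + 1L,
                                what = "column 'abundance'")
    ids <- unique(raw$protein_id)
    reps <- unique(raw$replicate)
    mat <- matrix(NA_real_, nrow = length(ids),
                  ncol = length(reps) * length(lonChannels()),
                  dimnames = list(ids, paste(rep(reps, each = 10),
                                             rep(lonChannels(), length(reps)),
                                             sep = ":")))
    mat[cbind(match(raw$protein_id, ids),
              match(paste(raw$replicate, raw$channel, sep = ":"),
                    colnames(mat)))] <- vals
    LonScreenExperiment(mat,
                        replicate = rep(reps, each = 10),
                        channel = rep(lonChannels(), length(reps)))
}

#' Write a protein abundance table
#'
#' Inverse of [readAbundanceTable()]. In the wide dialect missing cells are
#' written as empty strings; in the long dialect missing cells are simply
#' omitted (one row per measured value).
#'
#' @param x a [LonScreenExperiment-class].
#' @param path output path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(x, path, dialect = c("wide", "long")) {
    dialect <- match.arg(dialect)
    a <- abundances(x)
    if (dialect == "wide") {
        out <- data.frame(protein_id = rownames(a), a,
                          check.names = FALSE, stringsAsFactors = FALSE)
        write.table(out, path, sep = "\t", quote = FALSE, na = "",
                    row.names = FALSE, fileEncoding = "UTF-8")
    } else {
        cd <- SummarizedExperiment::colData(x)
        idx <- which(!is.na(a), arr.ind = TRUE)
        out <- data.frame(protein_id = rownames(a)[idx[, 1]],
                          replicate = as.character(cd$replicate)[idx[, 2]],
                          channel = as.character(cd$channel)[idx[, 2]],
                          abundance = a[idx],
                          stringsAsFactors = FALSE)
        out <- out[order(match(out$protein_id, rownames(a)),
                         match(out$replicate,
                               unique(as.character(cd$replicate))),
                         match(out$channel, lonChannels())), ]
        write.table(out, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, fileEncoding = "UTF-8")
    }
    invisible(path)
}

#' Write / read the candidate table
#'
#' The candidate table has one row per detected protein with a fixed,
#' documented column order: `protein_id`, the replicate-averaged ratios
#' `r_steady`, `r_depl`, `r_oe`, `r_wt_decay`, the derived
#' `r_stabilization`, the four criterion flags `c_steady`, `c_depl`,
#' `c_oe`, `c_stab`, the criteria count `n_criteria`, the `putative` call
#' and the functional `category` (`"unclassified"` when unmapped).
#'
#' @param table a candidate table as returned by [selectCandidates()].
#' @param path file path.
#' @return `writeCandidates()` returns `path` invisibly; `readCandidates()`
#'   returns the candidate table data frame.
#' @export
writeCandidates <- function(table, path) {
    missing_cols <- setdiff(.candidateColumns, colnames(table))
    if (length(missing_cols))
        stop("candidate table lacks column(s): ",
             paste(missing_cols, collapse = ", "))
    write.table(table[, .candidateColumns, drop = FALSE], path,
                sep = "\t", quote = FALSE, na = "NA",
                row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeCandidates
#' @export
readCandidates <- function(path) {
    out <- read.delim(path, sep = "\t", check.names = FALSE,
                      na.strings = "NA", stringsAsFactors = FALSE,
                      colClasses = c(protein_id = "character",
                                     category = "character"),
                      fileEncoding = "UTF-8")
    if (!identical(colnames(out), .candidateColumns))
        stop("not a candidate table (unexpected columns): ", path)
    for (cc in c("c_steady", "c_depl", "c_oe", "c_stab", "putative"))
        out[[cc]] <- as.logical(out[[cc]])
    out$n_criteria <- as.integer(out$n_criteria)
    out
}

#' Read a protein-to-functional-category map
#'
#' Two-column TSV (`protein_id`, `category`). Repeated consistent rows
#' collapse to one entry; a protein listed with two different categories is
#' an error. Proteins absent from the map are later tallied as
#' `"unclassified"`.
#'
#' @param path file path.
#' @return Named character vector mapping protein identifier to category
#'   label; the order of first appearance of labels is the display order.
#' @export
readCategoryMap <- function(path) {
    if (!file.exists(path))
        stop("category map not found: ", path)
    raw <- read.delim(path, sep = "\t", colClasses = "character",
                      check.names = FALSE, na.strings = NULL,
                      fileEncoding = "UTF-8")
    if (ncol(raw) < 2L ||
        !all(c("protein_id", "category") %in% colnames(raw)))
        stop("category map must have columns 'protein_id' and 'category': ",
             path)
    raw <- unique(raw[, c("protein_id", "category")])
    dup <- unique(raw$protein_id[duplicated(raw$protein_id)])
    if (length(dup))
        stop("protein(s) mapped to conflicting categories: ",
             paste(dup, collapse = ", "))
    stats::setNames(raw$category, raw$protein_id)
}
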