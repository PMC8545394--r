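## Functional-category bookkeeping: tally a protein set by category and
## compare candidate proportions against the detected universe. Purely
## descriptive -- the screen presents category shifts as proportions, with
## an optional hypergeometric enrichment test offered beyond that.

#' Tally a protein set by functional category
#'
#' Counts the proteins of `proteins` per category of `map`; proteins
#' absent from the map land in `"unclassified"`. Proportions are counts
#' over `length(proteins)` and sum to 1 (0 for an empty set).
#'
#' @param proteins character vector of protein identifiers.
#' @param map named character vector from [readCategoryMap()].
#' @return Data frame with columns `category`, `count`, `proportion`;
#'   categories in map display order, then `"unclassified"`. Includes
#'   zero-count rows so two tallies over the same map share a label space.
#' @examples
#' map <- c(P1 = "cell cycle", P2 = "motility")
#' tallyCategories(c("P1", "P2", "P3"), map)
#' @export
tallyCategories <- function(proteins, map) {
    labels <- c(unique(unname(map)), "unclassified")
    assigned <- ifelse(proteins %in% names(map),
                       unname(map[proteins]), "unclassified")
    count <- vapply(labels, function(l) sum(assigned == l), 0L)
    data.frame(category = labels,
               count = count,
               proportion = if (length(proteins))
                   count / length(proteins) else rep(0, length(labels)),
               row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Compare category proportions between candidates and the universe
#'
#' For each category, reports its proportion among the candidate set, its
#' proportion among the detected universe, and the ratio of the two (the
#' relative over/under-representation of the category among candidates).
#' Descriptive by default; `test = TRUE` adds a one-sided hypergeometric
#' enrichment p-value per category, an extension beyond the original
#' proportion-based presentation.
#'
#' @param candidates tally of the candidate set from [tallyCategories()].
#' @param universe tally of the detected universe over the same map.
#' @param test logical; add hypergeometric enrichment p-values.
#' @return Data frame with columns `category`, `prop_candidates`,
#'   `prop_universe`, `ratio` (and `p_enrichment` when `test`). The ratio
#'   is 0 for categories absent from candidates and `NA` where the
#'   universe proportion is 0.
#' @export
compareProportions <- function(candidates, universe, test = FALSE) {
    if (!identical(candidates$category, universe$category))
        stop("tallies must share one category label space ",
             "(tally both sets with the same map)")
    ratio <- ifelse(universe$proportion > 0,
                    candidates$proportion / universe$proportion,
                    ifelse(candidates$proportion == 0, NA_real_, Inf))
    out <- data.frame(category = candidates$category,
                      prop_candidates = candidates$proportion,
                      prop_universe = universe$proportion,
                      ratio = ratio,
                      stringsAsFactors = FALSE)
    if (isTRUE(test)) {
        n_cand <- sum(candidates$count)
        n_univ <- sum(universe$count)
        out$p_enrichment <- mapply(function(q, m) {
            stats::phyper(q - 1, m, n_univ - m, n_cand, lower.tail = FALSE)
        }, candidates$count, universe$count)
    }
    out
}
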