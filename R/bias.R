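# Relative homeolog expression is binned into seven biased-expression
# categories of the N-fraction plus a distinct "no expression" state when
# both copies are silent. Complete bias against one copy (<5% or >=95%) is
# the operational definition of that copy being silenced in the tissue.

BIAS_LEVELS <- c("COMPLETE_9", "STRONG_9", "BIASED_9", "EQUIVALENT",
                 "BIASED_N", "STRONG_N", "COMPLETE_N", "NO_EXPRESSION")
BIAS_BREAKS <- c(0, 5, 20, 40, 60, 80, 95, 100)

#' Bias category levels
#'
#' The seven biased-expression categories of the N-fraction, in ascending
#' order, plus `NO_EXPRESSION`: `COMPLETE_9` \[0, 5), `STRONG_9` \[5, 20),
#' `BIASED_9` \[20, 40), `EQUIVALENT` \[40, 60), `BIASED_N` \[60, 80),
#' `STRONG_N` \[80, 95), `COMPLETE_N` \[95, 100\]. Intervals are left-closed
#' (half-open) with the top interval closed, so every fraction in
#' `[0, 100]` maps to exactly one category.
#'
#' @return Character vector of the eight category labels.
#' @export
bias_levels <- function() BIAS_LEVELS

#' Classify an N-fraction into a bias category
#'
#' Undefined fractions (`NA`, i.e. both copies below detection) map to
#' `NO_EXPRESSION`. Fractions outside `[0, 100]` are an error.
#'
#' @param n_fraction Numeric vector of percentages in `[0, 100]`, `NA` for
#'   undefined.
#' @return Factor with levels [bias_levels()].
#' @export
#' @examples
#' classify_bias(c(50, 97, 3, NA))
classify_bias <- function(n_fraction) {
  stopifnot(is.numeric(n_fraction) || all(is.na(n_fraction)))
  x <- as.numeric(n_fraction)
  if (any(!is.na(x) & (x < 0 | x > 100)))
    stop("n_fraction outside [0, 100]")
  cat <- cut(x, breaks = BIAS_BREAKS, labels = BIAS_LEVELS[1:7],
             right = FALSE, include.lowest = TRUE)
  out <- as.character(cat)
  out[is.na(x)] <- "NO_EXPRESSION"
  factor(out, levels = BIAS_LEVELS)
}

#' Derive per-homeolog silencing calls from a bias category
#'
#' A homeolog is called silenced only under complete bias against it:
#' `COMPLETE_9` silences N, `COMPLETE_N` silences 9. `NO_EXPRESSION`
#' (both copies off) sets neither allele-specific silencing flag — it is a
#' distinct state, not silencing of one homeolog relative to the other.
#'
#' @param category Factor or character vector of bias categories.
#' @return data.frame with logical columns `silenced_N`, `silenced_9`,
#'   `expressed_N`, `expressed_9`.
#' @export
call_silencing <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category[!is.na(category)]), BIAS_LEVELS)
  if (length(bad)) stop("unknown bias category: ", paste(bad, collapse = ", "))
  silenced_N <- category == "COMPLETE_9"
  silenced_9 <- category == "COMPLETE_N"
  noexp <- category == "NO_EXPRESSION"
  data.frame(
    silenced_N = silenced_N,
    silenced_9 = silenced_9,
    expressed_N = !silenced_N & !noexp,
    expressed_9 = !silenced_9 & !noexp
  )
}

#' Classify assay records and derive silencing calls
#'
#' Adds `n_fraction` (computed from signals where needed), the bias
#' `category`, and the four per-homeolog silencing/expression flags to a
#' table of assay records.
#'
#' @param records Assay records (see [read_assay_table()]).
#' @param detection_limit Passed to [compute_n_fraction()] when fractions
#'   must be computed from signals.
#' @return The records with columns `n_fraction`, `category`, `silenced_N`,
#'   `silenced_9`, `expressed_N`, `expressed_9` appended ("calls").
#' @export
classify_records <- function(records, detection_limit = 0) {
  out <- records
  if (!"n_fraction" %in% names(out)) out$n_fraction <- NA_real_
  need <- is.na(out$n_fraction)
  if (any(need) && all(c("signal_N", "signal_9") %in% names(out))) {
    sig <- !is.na(out$signal_N) & !is.na(out$signal_9)
    idx <- which(need & sig)
    if (length(idx))
      out$n_fraction[idx] <- compute_n_fraction(out$signal_N[idx],
                                                out$signal_9[idx],
                                                detection_limit)
  }
  if ("below_detection" %in% names(out))
    out$n_fraction[out$below_detection] <- NA_real_
  if (!"stage" %in% names(out) || anyNA(out$stage))
    out$stage <- unname(TISSUE_STAGE[as.character(out$tissue)])
  out$category <- classify_bias(out$n_fraction)
  out <- cbind(out, call_silencing(out$category))
  out
}

#' Tabulate expression-state distributions
#'
#' Counts and row-normalized proportions of bias categories within groups of
#' records (by default per plant group x tissue), mirroring stacked state
#' distributions across tissues and plant groups.
#'
#' @param calls Classified records from [classify_records()].
#' @param by Character vector of grouping columns (default
#'   `c("group", "tissue")`).
#' @return data.frame with the grouping columns, `category`, `n`, and
#'   `proportion` (summing to 1 within each grouping cell).
#' @export
tabulate_states <- function(calls, by = c("group", "tissue")) {
  if (nrow(calls) == 0L) {
    out <- stats::setNames(
      data.frame(matrix(character(0), 0, length(by)), character(0),
                 integer(0), numeric(0), stringsAsFactors = FALSE),
      c(by, "category", "n", "proportion"))
    return(out)
  }
  stopifnot(all(by %in% names(calls)), "category" %in% names(calls))
  f <- c(lapply(calls[by], as.character),
         list(category = factor(calls$category, levels = BIAS_LEVELS)))
  tab <- as.data.frame(table(f), stringsAsFactors = FALSE)
  names(tab)[ncol(tab)] <- "n"
  cell <- interaction(tab[by], drop = FALSE)
  tot <- stats::ave(tab$n, cell, FUN = sum)
  tab$proportion <- ifelse(tot > 0, tab$n / tot, NA_real_)
  tab <- tab[tot > 0, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Equal vs unequal locus expression patterns
#'
#' A locus (gene x individual) shows an "equal" pattern when strictly more
#' than half of its calls with a defined N-fraction are `EQUIVALENT`
#' (40-60% N); otherwise "unequal". Loci with no defined fractions are
#' `"NO_CALLS"`. This is the per-locus summary behind statements like
#' "x% of loci showed unequal expression of the two copies".
#'
#' @param calls Classified records from [classify_records()].
#' @return data.frame with one row per gene x individual: `gene_id`,
#'   `individual_id`, `group`, `n_defined`, `n_equivalent`, `pattern`.
#' @export
locus_patterns <- function(calls) {
  key <- paste(calls$gene_id, calls$individual_id, sep = "\r")
  defined <- !is.na(calls$n_fraction)
  equiv <- defined & calls$category == "EQUIVALENT"
  agg <- function(x) as.vector(tapply(x, key, sum))
  ord <- !duplicated(key)
  n_def <- agg(defined)
  n_eq <- agg(equiv)
  # tapply sorts by key; align the representative rows the same way
  rep_rows <- calls[ord, c("gene_id", "individual_id", "group")]
  rep_key <- paste(rep_rows$gene_id, rep_rows$individual_id, sep = "\r")
  o <- order(rep_key)
  rep_rows <- rep_rows[o, ]
  out <- data.frame(rep_rows,
                    n_defined = n_def, n_equivalent = n_eq,
                    stringsAsFactors = FALSE)
  out$pattern <- ifelse(out$n_defined == 0L, "NO_CALLS",
                        ifelse(out$n_equivalent * 2L > out$n_defined,
                               "EQUAL", "UNEQUAL"))
  rownames(out) <- NULL
  out
}
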