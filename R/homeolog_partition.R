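#' Run the full homeolog expression partitioning analysis
#'
#' One-call pipeline: classifies every measurement's N-fraction into bias
#' categories, derives per-homeolog silencing calls, detects TSS /
#' reciprocal-TSS / nonfunctionalization events over the standard tissue
#' sets, scores per-individual TSS percentages, summarizes them per plant
#' group, and runs the default nonparametric group comparisons.
#'
#' @param records Assay records from [read_assay_table()] or
#'   [simulate_assays()], optionally pre-filtered by [filter_assays()].
#' @param sets Named list of tissue sets (default [tissue_sets()]).
#' @param detection_limit Passed to [classify_records()].
#' @param denominator TSS denominator convention (see [score_tss()]).
#' @param alpha Significance level for the comparison table.
#' @param contrasts Optional contrast design for [compare_all()]; `NULL`
#'   (default) uses [default_contrasts()]; `NA` skips testing.
#' @return Object of class `homeolog_partition` with components `calls`,
#'   `events`, `scores`, `groups` (group summary), `tests`, `states`
#'   (expression-state table), `loci` (equal/unequal locus patterns), and
#'   `sets`.
#' @export
#' @examples
#' sim <- simulate_assays(paper_like_config(seed = 42))
#' fit <- homeolog_partition(sim$records)
#' fit
#' head(summary(fit)$groups)
homeolog_partition <- function(records, sets = tissue_sets(),
                               detection_limit = 0,
                               denominator = "homeolog_tissue",
                               alpha = 0.05, contrasts = NULL) {
  calls <- classify_records(records, detection_limit = detection_limit)
  events <- partition_events(calls, sets = sets)
  scores <- do.call(rbind, lapply(names(sets), function(nm)
    score_tss(events, calls, sets[[nm]], set_name = nm,
              denominator = denominator)))
  rownames(scores) <- NULL
  groups <- summarize_groups(scores)
  tests <- if (length(contrasts) == 1L && is.na(contrasts)) NULL
    else compare_all(scores,
                     design = if (is.null(contrasts))
                       default_contrasts(scores) else contrasts,
                     alpha = alpha)
  structure(list(
    calls = calls, events = events, scores = scores, groups = groups,
    tests = tests, states = tabulate_states(calls),
    loci = locus_patterns(calls), sets = sets, alpha = alpha
  ), class = "homeolog_partition")
}

#' @export
print.homeolog_partition <- function(x, ...) {
  cat("Homeolog expression partitioning\n")
  cat(sprintf("  %d calls (%d genes, %d individuals), %d events over %d tissue sets\n",
              nrow(x$calls), length(unique(x$calls$gene_id)),
              length(unique(x$calls$individual_id)), nrow(x$events),
              length(x$sets)))
  kinds <- table(x$events$kind)
  cat("  events: ",
      paste(sprintf("%s=%d", names(kinds), as.integer(kinds)),
            collapse = ", "), "\n", sep = "")
  cat("  group mean TSS (%) by tissue set:\n")
  g <- x$groups
  g$mean_tss <- round(g$mean_tss, 2)
  g$se_tss <- round(g$se_tss, 2)
  print(g, row.names = FALSE)
  invisible(x)
}

#' @export
summary.homeolog_partition <- function(object, ...) {
  loci <- object$loci[object$loci$pattern != "NO_CALLS", , drop = FALSE]
  pct_unequal <- vapply(split(loci, loci$group), function(l)
    100 * mean(l$pattern == "UNEQUAL"), numeric(1))
  out <- list(
    groups = object$groups,
    tests = object$tests,
    states = object$states,
    pct_unequal_loci = pct_unequal,
    reciprocal_cases = count_reciprocal(object$events),
    reciprocal_by_set = table(
      object$events$tissue_set[object$events$kind == "RECIPROCAL_TSS"])
  )
  class(out) <- "summary.homeolog_partition"
  out
}

#' @export
print.summary.homeolog_partition <- function(x, ...) {
  cat("Group-level TSS summary:\n")
  print(x$groups, row.names = FALSE)
  cat("\nUnequal-expression loci (% of gene x individual, per group):\n")
  print(round(x$pct_unequal_loci, 1))
  cat("\nReciprocal TSS (subfunctionalization) cases:",
      x$reciprocal_cases, "\n")
  if (!is.null(x$tests) && nrow(x$tests)) {
    cat("\nSignificant contrasts (unadjusted p):\n")
    sig <- x$tests[x$tests$significant, c("contrast", "test", "p_value")]
    if (nrow(sig)) print(sig, row.names = FALSE) else cat("  none\n")
  }
  invisible(x)
}

#' Plot group-level TSS percentages
#'
#' Bar plot of mean TSS percentage per plant group with standard-error
#' whiskers, one panel per tissue set.
#'
#' @param x A `homeolog_partition` object.
#' @param sets Tissue-set labels to plot (default: all scored sets).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the group summary table.
#' @export
plot.homeolog_partition <- function(x, sets = unique(x$groups$tissue_set),
                                    ...) {
  g <- x$groups[x$groups$tissue_set %in% sets, , drop = FALSE]
  old <- graphics::par(mfrow = c(1, length(sets)))
  on.exit(graphics::par(old))
  for (s in sets) {
    gi <- g[g$tissue_set == s, , drop = FALSE]
    ylim <- c(0, max(gi$mean_tss + ifelse(is.na(gi$se_tss), 0, gi$se_tss)) *
                1.2 + 1e-9)
    mid <- graphics::barplot(gi$mean_tss, names.arg = gi$group,
                             ylab = "TSS (%)", main = s, ylim = ylim, ...)
    ok <- !is.na(gi$se_tss) & gi$se_tss > 0
    if (any(ok))
      graphics::arrows(mid[ok], gi$mean_tss[ok] - gi$se_tss[ok],
                       mid[ok], gi$mean_tss[ok] + gi$se_tss[ok],
                       angle = 90, code = 3, length = 0.05)
  }
  invisible(g)
}
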