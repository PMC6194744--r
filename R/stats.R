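# Nonparametric group comparisons of TSS scores. Small tie-free samples are
# tested exactly; larger or tied samples use the normal approximation with
# tie and continuity corrections. Two-sided throughout. No multiplicity
# adjustment by default; compare_all() also emits Holm-adjusted p-values.

new_tss_htest <- function(test, statistic, p_value, n1, n2, alpha, exact,
                          degenerate = FALSE) {
  structure(list(test = test, statistic = statistic,
                 p_value = min(1, p_value), n1 = n1, n2 = n2, alpha = alpha,
                 significant = p_value < alpha, exact = exact,
                 degenerate = degenerate),
            class = "tss_htest")
}

#' @export
print.tss_htest <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %s, n = %d/%d, p = %.4g%s%s\n",
              x$test, if (x$exact) "exact" else "normal approximation",
              format(x$statistic), x$n1, x$n2, x$p_value,
              if (x$significant) " *" else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two independent samples. The p-value is exact
#' (full enumeration of rank assignments) when `n1 + n2 <= 12` and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A `tss_htest` with fields `test`, `statistic` (the U statistic of
#'   `sample_a`), `p_value`, `n1`, `n2`, `significant`, `exact`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12))  # exact p = 0.1
mann_whitney <- function(sample_a, sample_b, alpha = 0.05) {
  stopifnot(is.numeric(sample_a), is.numeric(sample_b),
            length(sample_a) > 0L, length(sample_b) > 0L,
            !anyNA(sample_a), !anyNA(sample_b))
  n1 <- length(sample_a); n2 <- length(sample_b)
  exact <- (n1 + n2 <= 12L) && !anyDuplicated(c(sample_a, sample_b))
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  new_tss_htest("MANN_WHITNEY", unname(ht$statistic), ht$p.value,
                n1, n2, alpha, exact)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired comparison. Zero differences are dropped; with `k`
#' remaining pairs the p-value is exact (enumeration of the `2^k` sign
#' assignments) when `k <= 12` and the absolute differences are tie-free,
#' otherwise the tie- and continuity-corrected normal approximation is used.
#' If every difference is zero the result is degenerate: `p = 1`, flagged.
#'
#' @param x Either a numeric vector of first measurements (with `y` the
#'   paired second measurements) or a two-column matrix/data.frame of pairs.
#' @param y Optional numeric vector paired with `x`.
#' @param alpha Significance level for the `significant` flag.
#' @return A `tss_htest`; `n1` is the number of nonzero pairs, `n2` the
#'   number dropped as zero.
#' @export
#' @examples
#' wilcoxon_matched(c(4, 5, 6), c(3, 3, 3))  # differences +1, +2, +3
wilcoxon_matched <- function(x, y = NULL, alpha = 0.05) {
  if (is.null(y)) {
    stopifnot(ncol(x) == 2L)
    y <- x[, 2L]; x <- x[, 1L]
  }
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) > 0L, !anyNA(x), !anyNA(y))
  d <- x - y
  nz <- d[d != 0]
  n_zero <- length(d) - length(nz)
  if (length(nz) == 0L)
    return(new_tss_htest("WILCOXON_MATCHED", NA_real_, 1, 0L, n_zero, alpha,
                         exact = TRUE, degenerate = TRUE))
  exact <- (length(nz) <= 12L) && !anyDuplicated(abs(nz))
  ht <- suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = TRUE))
  new_tss_htest("WILCOXON_MATCHED", unname(ht$statistic), ht$p.value,
                length(nz), n_zero, alpha, exact)
}

#' Default contrast design for TSS scores
#'
#' Builds the comparisons used throughout the analysis: Mann-Whitney tests
#' between every pair of plant groups within each tissue set; Mann-Whitney
#' root-vs-leaf development-TSS within each group; and Wilcoxon
#' matched-pairs tillering-vs-booting contrasts within each group (the same
#' individuals are sampled at both stages).
#'
#' @param scores Per-individual scores from [score_tss()].
#' @return data.frame design accepted by [compare_all()], with columns
#'   `contrast`, `test`, `group_a`, `set_a`, `group_b`, `set_b`.
#' @export
default_contrasts <- function(scores) {
  design <- list()
  add <- function(contrast, test, ga, sa, gb, sb)
    design[[length(design) + 1L]] <<- data.frame(
      contrast = contrast, test = test, group_a = ga, set_a = sa,
      group_b = gb, set_b = sb, stringsAsFactors = FALSE)
  sets <- unique(scores$tissue_set)
  for (s in sets) {
    gs <- sort(unique(scores$group[scores$tissue_set == s]))
    if (length(gs) >= 2L) {
      pairs <- utils::combn(gs, 2L)
      for (j in seq_len(ncol(pairs)))
        add(sprintf("%s vs %s [%s]", pairs[1L, j], pairs[2L, j], s),
            "MANN_WHITNEY", pairs[1L, j], s, pairs[2L, j], s)
    }
  }
  if (all(c("root_dev", "leaf_dev") %in% sets)) {
    for (g in sort(unique(scores$group)))
      add(sprintf("root vs leaf development-TSS [%s]", g),
          "MANN_WHITNEY", g, "root_dev", g, "leaf_dev")
  }
  if (all(c("tillering", "booting") %in% sets)) {
    for (g in sort(unique(scores$group)))
      add(sprintf("tillering vs booting [%s]", g),
          "WILCOXON_MATCHED", g, "tillering", g, "booting")
  }
  if (!length(design))
    return(data.frame(contrast = character(0), test = character(0),
                      group_a = character(0), set_a = character(0),
                      group_b = character(0), set_b = character(0)))
  do.call(rbind, design)
}

#' Run a set of group comparisons on TSS scores
#'
#' Executes each contrast of the design: Mann-Whitney for independent
#' comparisons (between groups, or root vs leaf within a group) and Wilcoxon
#' matched-pairs for within-individual stage contrasts (paired by
#' `individual_id`). P-values are reported unadjusted, with a Holm-adjusted
#' column alongside; `significant` uses the unadjusted p-value.
#'
#' @param scores Per-individual scores from [score_tss()].
#' @param design Contrast design (default [default_contrasts()]).
#' @param alpha Significance level (default 0.05).
#' @return data.frame: `contrast`, `test`, `exact`, `statistic`, `n1`, `n2`,
#'   `p_value`, `p_holm`, `significant`. Contrasts with an empty cell are
#'   skipped with a warning.
#' @export
compare_all <- function(scores, design = default_contrasts(scores),
                        alpha = 0.05) {
  cell <- function(g, s)
    scores[scores$group == g & scores$tissue_set == s, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    a <- cell(d$group_a, d$set_a); b <- cell(d$group_b, d$set_b)
    if (nrow(a) == 0L || nrow(b) == 0L) {
      warning("skipping contrast with missing cell: ", d$contrast)
      next
    }
    ht <- if (d$test == "WILCOXON_MATCHED") {
      common <- intersect(a$individual_id, b$individual_id)
      if (length(common) == 0L) {
        warning("skipping paired contrast with no common individuals: ",
                d$contrast)
        next
      }
      wilcoxon_matched(a$percent_tss[match(common, a$individual_id)],
                       b$percent_tss[match(common, b$individual_id)],
                       alpha = alpha)
    } else {
      mann_whitney(a$percent_tss, b$percent_tss, alpha = alpha)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = d$contrast, test = ht$test, exact = ht$exact,
      statistic = ht$statistic, n1 = ht$n1, n2 = ht$n2,
      p_value = ht$p_value, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(contrast = character(0), test = character(0),
                      exact = logical(0), statistic = numeric(0),
                      n1 = integer(0), n2 = integer(0), p_value = numeric(0),
                      p_holm = numeric(0), significant = logical(0)))
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}
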