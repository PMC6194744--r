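# Tissue-specific silencing (TSS) partitioning. Within a tissue set, a
# homeolog shows TSS when it is silenced (complete bias against it) in at
# least one measured tissue while being expressed in at least one other;
# silencing in every measured tissue of the set is nonfunctionalization, and
# TSS of both homeologs of a gene within the same set is reciprocal TSS
# (subfunctionalization). "No expression" tissues (both copies off) are
# neutral: they count as neither silenced nor expressed for either homeolog.

#' Standard tissue sets for silencing partitioning
#'
#' `tillering` (`L1`, `R1`) and `booting` (`L2`, `R2`, `F`, `S`) score TSS
#' within a growth stage; `all_six` scores it across every assayed tissue;
#' `leaf_dev` (`L1` vs `L2`) and `root_dev` (`R1` vs `R2`) contrast the same
#' organ across the two stages, isolating development-driven silencing.
#'
#' @return Named list of tissue character vectors.
#' @export
tissue_sets <- function() {
  list(
    tillering = c("L1", "R1"),
    booting = c("L2", "R2", "F", "S"),
    all_six = TISSUES,
    leaf_dev = c("L1", "L2"),
    root_dev = c("R1", "R2")
  )
}

# Detection kernel for one gene x individual. Takes parallel vectors over
# the measured tissues of a set; returns a list of events (possibly empty).
# Kept free of data.frame construction: it runs tens of thousands of times
# in the oracle-equivalence checks.
detect_one <- function(tissue, silenced_N, silenced_9, no_expr) {
  events <- list()
  tss_n <- FALSE
  tss_9 <- FALSE
  for (h in c("N", "9")) {
    sil <- if (h == "N") silenced_N else silenced_9
    expr <- !sil & !no_expr
    n_sil <- sum(sil)
    if (n_sil == 0L) next
    if (n_sil == length(tissue)) {
      events[[length(events) + 1L]] <- list(
        homeolog = h, kind = "NONFUNCTIONALIZATION",
        silenced_in = tissue[sil], expressed_in = character(0))
    } else if (any(expr)) {
      events[[length(events) + 1L]] <- list(
        homeolog = h, kind = "TSS",
        silenced_in = tissue[sil], expressed_in = tissue[expr])
      if (h == "N") tss_n <- TRUE else tss_9 <- TRUE
    }
    # silenced somewhere, expressed nowhere, but some no-expression tissues:
    # neither TSS (no expressed contrast) nor nonfunctionalization (the
    # no-expression tissues are not evidence of h-specific silencing).
  }
  if (tss_n && tss_9) {
    events[[length(events) + 1L]] <- list(
      homeolog = NA_character_, kind = "RECIPROCAL_TSS",
      silenced_in = character(0), expressed_in = character(0))
  }
  events
}

#' Detect tissue-specific silencing events
#'
#' Scans classified calls for TSS, nonfunctionalization, and reciprocal-TSS
#' events of each homeolog within a tissue set, per gene x individual.
#' Gene x individual pairs with fewer than two measured tissues in the set
#' are excluded (TSS is undefined without a contrast); their count is
#' attached as attribute `n_insufficient`.
#'
#' @param calls Classified records from [classify_records()].
#' @param tissue_set Character vector of tissues (see [tissue_sets()]).
#' @param set_name Label stored in the output's `tissue_set` column.
#' @return data.frame of events: `gene_id`, `individual_id`, `group`,
#'   `homeolog` (`NA` for reciprocal events), `tissue_set`, `kind`,
#'   `silenced_in`, `expressed_in` (comma-separated tissue lists).
#' @export
detect_tss <- function(calls, tissue_set, set_name = "set") {
  stopifnot(all(c("gene_id", "individual_id", "tissue",
                  "silenced_N", "silenced_9", "category") %in% names(calls)))
  cc <- calls[calls$tissue %in% tissue_set, , drop = FALSE]
  grp <- if ("group" %in% names(cc)) cc$group else rep(NA_character_, nrow(cc))
  key <- paste(cc$gene_id, cc$individual_id, sep = "\r")
  idx <- split(seq_len(nrow(cc)), key)
  noexp <- cc$category == "NO_EXPRESSION"

  gene <- character(0); ind <- character(0); group <- character(0)
  hom <- character(0); kind <- character(0)
  sil_in <- character(0); exp_in <- character(0)
  n_insufficient <- 0L
  for (rows in idx) {
    if (length(rows) < 2L) { n_insufficient <- n_insufficient + 1L; next }
    ev <- detect_one(cc$tissue[rows], cc$silenced_N[rows],
                     cc$silenced_9[rows], noexp[rows])
    for (e in ev) {
      gene <- c(gene, cc$gene_id[rows[1L]])
      ind <- c(ind, cc$individual_id[rows[1L]])
      group <- c(group, grp[rows[1L]])
      hom <- c(hom, e$homeolog)
      kind <- c(kind, e$kind)
      sil_in <- c(sil_in, paste(e$silenced_in, collapse = ","))
      exp_in <- c(exp_in, paste(e$expressed_in, collapse = ","))
    }
  }
  out <- data.frame(gene_id = gene, individual_id = ind, group = group,
                    homeolog = hom, tissue_set = rep(set_name, length(gene)),
                    kind = kind, silenced_in = sil_in, expressed_in = exp_in,
                    stringsAsFactors = FALSE)
  attr(out, "n_insufficient") <- n_insufficient
  out
}

#' Detect events across several tissue sets
#'
#' @param calls Classified records from [classify_records()].
#' @param sets Named list of tissue sets (default [tissue_sets()]).
#' @return Row-bound events across all sets (see [detect_tss()]).
#' @export
partition_events <- function(calls, sets = tissue_sets()) {
  stopifnot(length(sets) > 0L, !is.null(names(sets)))
  out <- do.call(rbind, lapply(names(sets), function(nm)
    detect_tss(calls, sets[[nm]], set_name = nm)))
  rownames(out) <- NULL
  out
}

# Count measured (gene, tissue) cells per individual for genes with >= 2
# measured tissues in the set; returns per-individual numerator/denominator
# building blocks shared by score_tss.
qualifying_cells <- function(calls, tissue_set) {
  cc <- calls[calls$tissue %in% tissue_set, , drop = FALSE]
  key <- paste(cc$gene_id, cc$individual_id, sep = "\r")
  per <- table(key)
  ok <- names(per)[per >= 2L]
  cc[key %in% ok, , drop = FALSE]
}

#' Score tissue-specific silencing per individual
#'
#' The TSS percentage of an individual over a tissue set is
#' `100 * numerator / denominator` where, under the default
#' `denominator = "homeolog_tissue"`, the denominator counts every measured
#' (gene, homeolog, tissue) triple in the set (genes needing at least two
#' measured tissues) and the numerator counts the triples in which that
#' homeolog is silenced in that tissue as part of a TSS event. Under
#' `denominator = "gene_tissue"`, a gene x tissue cell is counted once and is
#' in the numerator when either homeolog is TSS-silenced there.
#'
#' @param events Events from [detect_tss()] / [partition_events()].
#' @param calls The classified calls the events were derived from.
#' @param tissue_set Character vector of tissues.
#' @param set_name Label matching the events' `tissue_set` column.
#' @param homeolog `"both"` (default), `"N"` or `"9"`: restrict scoring to
#'   one homeolog (used for per-subgenome development-TSS summaries).
#' @param denominator `"homeolog_tissue"` (default) or `"gene_tissue"`.
#' @return data.frame per individual: `individual_id`, `group`,
#'   `tissue_set`, `numerator`, `denominator`, `percent_tss`.
#' @export
score_tss <- function(events, calls, tissue_set, set_name = "set",
                      homeolog = c("both", "N", "9"),
                      denominator = c("homeolog_tissue", "gene_tissue")) {
  homeolog <- match.arg(homeolog)
  denominator <- match.arg(denominator)
  cc <- qualifying_cells(calls, tissue_set)
  if (nrow(cc) == 0L)
    stop("insufficient data: no gene has >= 2 measured tissues in the set")
  ev <- events[events$tissue_set == set_name & events$kind == "TSS", ,
               drop = FALSE]
  if (homeolog != "both")
    ev <- ev[ev$homeolog == homeolog, , drop = FALSE]
  # numerator contributions: one per silenced tissue per TSS event
  if (nrow(ev)) {
    sil_list <- strsplit(ev$silenced_in, ",", fixed = TRUE)
    reps <- lengths(sil_list)
    num_df <- data.frame(
      individual_id = rep(ev$individual_id, reps),
      gene_id = rep(ev$gene_id, reps),
      homeolog = rep(ev$homeolog, reps),
      tissue = unlist(sil_list),
      stringsAsFactors = FALSE)
    # only count cells that qualify (gene had >= 2 measured tissues)
    qual_key <- paste(cc$gene_id, cc$individual_id, cc$tissue, sep = "\r")
    num_df <- num_df[paste(num_df$gene_id, num_df$individual_id,
                           num_df$tissue, sep = "\r") %in% qual_key, ,
                     drop = FALSE]
  } else {
    num_df <- data.frame(individual_id = character(0),
                         gene_id = character(0), homeolog = character(0),
                         tissue = character(0), stringsAsFactors = FALSE)
  }
  inds <- unique(calls$individual_id)
  grp_of <- calls$group[match(inds, calls$individual_id)]
  n_hom <- if (homeolog == "both") 2L else 1L
  numerator <- denominator_n <- integer(length(inds))
  for (i in seq_along(inds)) {
    cells <- cc[cc$individual_id == inds[i], , drop = FALSE]
    nd <- num_df[num_df$individual_id == inds[i], , drop = FALSE]
    if (denominator == "homeolog_tissue") {
      denominator_n[i] <- n_hom * nrow(cells)
      numerator[i] <- nrow(nd)
    } else {
      denominator_n[i] <- nrow(cells)
      numerator[i] <- length(unique(paste(nd$gene_id, nd$tissue, sep = "\r")))
    }
  }
  keep <- denominator_n > 0L
  if (!all(keep))
    warning("individual(s) without scorable genes dropped: ",
            paste(inds[!keep], collapse = ", "))
  out <- data.frame(
    individual_id = inds[keep], group = grp_of[keep],
    tissue_set = set_name,
    numerator = numerator[keep], denominator = denominator_n[keep],
    percent_tss = 100 * numerator[keep] / denominator_n[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Score development-specific silencing within an organ
#'
#' Contrasts the same organ across the two growth stages (`leaf`: `L1` vs
#' `L2`; `root`: `R1` vs `R2`). A homeolog counts when silenced at one stage
#' while expressed at the other; both stages must be measured for a gene to
#' enter the denominator.
#'
#' @param calls Classified records from [classify_records()].
#' @param organ `"leaf"` or `"root"`.
#' @param homeolog,denominator Passed to [score_tss()].
#' @return Per-individual scores (see [score_tss()]), with `tissue_set`
#'   `"leaf_dev"` or `"root_dev"`.
#' @export
score_development_tss <- function(calls, organ = c("leaf", "root"),
                                  homeolog = "both",
                                  denominator = "homeolog_tissue") {
  organ <- match.arg(organ)
  set_name <- paste0(organ, "_dev")
  set <- tissue_sets()[[set_name]]
  ev <- detect_tss(calls, set, set_name = set_name)
  score_tss(ev, calls, set, set_name = set_name, homeolog = homeolog,
            denominator = denominator)
}

#' Summarize TSS scores per plant group
#'
#' Group means of individual TSS percentages with standard errors
#' (sample SD / sqrt(n)), per tissue set. A group with a single individual
#' gets an `NA` standard error.
#'
#' @param scores Per-individual scores from [score_tss()].
#' @return data.frame: `group`, `tissue_set`, `n`, `mean_tss`, `se_tss`.
#' @export
summarize_groups <- function(scores) {
  stopifnot(all(c("group", "tissue_set", "percent_tss") %in% names(scores)))
  key <- interaction(scores$group, scores$tissue_set, drop = TRUE)
  parts <- split(scores, key)
  out <- do.call(rbind, lapply(parts, function(s) {
    n <- nrow(s)
    data.frame(group = s$group[1L], tissue_set = s$tissue_set[1L], n = n,
               mean_tss = mean(s$percent_tss),
               se_tss = if (n >= 2L) stats::sd(s$percent_tss) / sqrt(n)
                        else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$tissue_set, out$group), , drop = FALSE]
}

#' Count reciprocal-TSS (subfunctionalization) cases
#'
#' One case is one gene x individual x tissue set in which both homeologs
#' show TSS within the set.
#'
#' @param events Events from [detect_tss()] / [partition_events()].
#' @param groups Optional plant groups to restrict to (default: all).
#' @param sets Optional tissue-set labels to restrict to (default: all).
#' @return Integer count.
#' @export
count_reciprocal <- function(events, groups = NULL, sets = NULL) {
  ev <- events[events$kind == "RECIPROCAL_TSS", , drop = FALSE]
  if (!is.null(groups)) ev <- ev[ev$group %in% groups, , drop = FALSE]
  if (!is.null(sets)) ev <- ev[ev$tissue_set %in% sets, , drop = FALSE]
  nrow(ev)
}
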