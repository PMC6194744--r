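#' homeoTSS: homeolog expression partitioning in newly formed polyploids
#'
#' Analyse homeolog-specific expression assays in hybrids and synthetic
#' allopolyploids: calibration QC against known DNA mixes, relative-expression
#' bias classification, tissue-specific silencing (TSS) partitioning across
#' tissues and growth stages, nonparametric group comparisons, and a
#' ground-truthed synthetic-data generator.
#'
#' The main entry point is [homeolog_partition()]; individual pipeline stages
#' are exposed as [read_assay_table()], [calibrate_assays()],
#' [classify_records()], [detect_tss()], [score_tss()], [summarize_groups()]
#' and [compare_all()]. Synthetic datasets come from [simulate_assays()].
#'
#' @keywords internal
"_PACKAGE"

# Fixed experimental design vocabulary. Two tissues (mature leaf L1, root R1)
# are sampled at the tillering stage; mature leaf L2, root R2, flag leaf F and
# young spike S at the booting stage. The same individual is sampled at both
# stages, which is what makes development-specific contrasts paired.
TISSUES <- c("L1", "R1", "L2", "R2", "F", "S")

TISSUE_STAGE <- c(
  L1 = "TILLERING", R1 = "TILLERING",
  L2 = "BOOTING", R2 = "BOOTING", F = "BOOTING", S = "BOOTING"
)

# Tissue classes used by the simulator's silencing-rate map.
TISSUE_CLASS <- c(L1 = "leaf", R1 = "root", L2 = "leaf", R2 = "root",
                  F = "flag", S = "spike")

PLANT_GROUPS <- c("PARENT_N", "PARENT_9", "MIX", "F1", "NN99", "99NN")

#' Tissue-to-stage mapping of the sampling design
#'
#' Returns the fixed mapping from tissue labels to growth stages: `L1`, `R1`
#' (mature leaf and root) sampled at tillering; `L2`, `R2`, `F`, `S` (mature
#' leaf, root, flag leaf, young spike) at booting. An override can be supplied
#' to [read_assay_table()] for non-rice designs.
#'
#' @return Named character vector mapping tissue to stage.
#' @export
#' @examples
#' tissue_stage_map()
tissue_stage_map <- function() TISSUE_STAGE

#' Compute the N-fraction from allele-specific signals
#'
#' The relative contribution of the japonica-derived copy (N) to total
#' transcripts, `signal_n / (signal_n + signal_9) * 100`. The fraction is
#' undefined (`NA`) when both signals are zero or both fall below the
#' detection limit: such measurements represent "no expression" of either
#' copy, not a ratio.
#'
#' @param signal_n,signal_9 Nonnegative numeric vectors of allele-specific
#'   signal intensities (arbitrary units) for the N and 9 copies.
#' @param detection_limit Nonnegative scalar; signals strictly below it on
#'   BOTH alleles render the fraction undefined. Default 0 (only exact 0/0 is
#'   undefined).
#' @return Numeric vector of percentages in `[0, 100]`, `NA` where undefined.
#' @export
#' @examples
#' compute_n_fraction(30, 90)   # 25
#' compute_n_fraction(100, 0)   # 100
#' compute_n_fraction(0, 0)     # NA: no expression
compute_n_fraction <- function(signal_n, signal_9, detection_limit = 0) {
  stopifnot(is.numeric(signal_n), is.numeric(signal_9),
            length(detection_limit) == 1L, detection_limit >= 0)
  n <- max(length(signal_n), length(signal_9))
  signal_n <- rep_len(as.numeric(signal_n), n)
  signal_9 <- rep_len(as.numeric(signal_9), n)
  bad <- which(signal_n < 0 | signal_9 < 0)
  if (length(bad))
    stop("negative signal intensities at position(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  undef <- is_below_detection(signal_n, signal_9, detection_limit)
  out <- ifelse(undef, NA_real_, signal_n / (signal_n + signal_9) * 100)
  # one signal NA -> fraction NA (propagate missingness)
  out[is.na(signal_n) | is.na(signal_9)] <- NA_real_
  out
}

# TRUE where both signals are below detection (or exactly 0/0).
is_below_detection <- function(signal_n, signal_9, detection_limit) {
  both_zero <- !is.na(signal_n) & !is.na(signal_9) &
    signal_n == 0 & signal_9 == 0
  both_low <- !is.na(signal_n) & !is.na(signal_9) &
    signal_n < detection_limit & signal_9 < detection_limit
  both_zero | both_low
}

#' Read and validate a long-format homeolog assay table
#'
#' Reads a tab-separated table with one row per gene x individual x tissue
#' measurement. Required columns: `gene_id`, `individual_id`, `group`,
#' `tissue`, and either both of `signal_N`, `signal_9` or `n_fraction`
#' (rows may use either form). Optional columns: `pathway`, `stage`.
#' Missing values are empty fields.
#'
#' Validation enforces the fixed tissue-to-stage mapping (see
#' [tissue_stage_map()]), uniqueness of (gene, individual, tissue), known
#' group labels, signal nonnegativity and fraction range; when a row carries
#' both signals and an `n_fraction`, the two must agree within `1e-6`
#' percentage points. Rows where both signals are below `detection_limit`
#' are retained and flagged `below_detection`; they classify downstream as
#' `NO_EXPRESSION`.
#'
#' @param path Path to a TSV file.
#' @param detection_limit Nonnegative scalar passed to [compute_n_fraction()].
#' @param tissue_stage Optional named character vector overriding the default
#'   tissue-to-stage mapping (for non-rice designs).
#' @return A data.frame of validated records with columns `gene_id`,
#'   `pathway`, `individual_id`, `group`, `tissue`, `stage`, `signal_N`,
#'   `signal_9`, `n_fraction`, `below_detection`.
#' @export
read_assay_table <- function(path, detection_limit = 0, tissue_stage = NULL) {
  stopifnot(file.exists(path), detection_limit >= 0)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_assay_records(df, detection_limit = detection_limit,
                         tissue_stage = tissue_stage)
}

#' Validate in-memory assay records
#'
#' Same contract as [read_assay_table()] for a data.frame already in memory;
#' used internally and by the simulator round-trip.
#'
#' @inheritParams read_assay_table
#' @param df A data.frame with the assay-table columns.
#' @return Validated, standardized records (see [read_assay_table()]).
#' @export
validate_assay_records <- function(df, detection_limit = 0,
                                   tissue_stage = NULL) {
  if (is.null(tissue_stage)) tissue_stage <- TISSUE_STAGE
  required <- c("gene_id", "individual_id", "group", "tissue")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("assay table format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  has_signals <- all(c("signal_N", "signal_9") %in% names(df))
  has_fraction <- "n_fraction" %in% names(df)
  if (!has_signals && !has_fraction)
    stop("assay table format error: need columns signal_N and signal_9, ",
         "or n_fraction")
  n <- nrow(df)
  line <- seq_len(n) + 1L  # +1 for the header row
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows))
      c(problems, paste0(what, " (line ", paste(line[rows], collapse = ", "),
                         ")"))
    else problems
  }

  sn <- if (has_signals) as.numeric(df$signal_N) else rep(NA_real_, n)
  s9 <- if (has_signals) as.numeric(df$signal_9) else rep(NA_real_, n)
  fr <- if (has_fraction) as.numeric(df$n_fraction) else rep(NA_real_, n)

  sig_present <- !is.na(sn) & !is.na(s9)
  frac_present <- !is.na(fr)
  problems <- note(which(!sig_present & !frac_present),
                   "row has neither both signals nor n_fraction")
  problems <- note(which(xor(!is.na(sn), !is.na(s9))),
                   "row has only one of signal_N/signal_9")
  problems <- note(which(sig_present & (sn < 0 | s9 < 0)),
                   "negative signal intensity")
  problems <- note(which(frac_present & (fr < 0 | fr > 100)),
                   "n_fraction outside [0, 100]")
  problems <- note(which(!df$tissue %in% names(tissue_stage)),
                   "unknown tissue label")
  problems <- note(which(!df$group %in% PLANT_GROUPS),
                   "unknown plant group")
  if ("stage" %in% names(df)) {
    expected <- unname(tissue_stage[df$tissue])
    bad <- which(!is.na(df$stage) & !is.na(expected) & df$stage != expected)
    problems <- note(bad, "tissue/stage contradiction")
  }
  key <- paste(df$gene_id, df$individual_id, df$tissue, sep = "\r")
  problems <- note(which(duplicated(key)),
                   "duplicate (gene_id, individual_id, tissue)")
  # consistency of redundant rows
  both <- which(sig_present & frac_present)
  if (length(both)) {
    implied <- compute_n_fraction(sn[both], s9[both], detection_limit)
    incons <- both[!is.na(implied) & abs(implied - fr[both]) > 1e-6]
    problems <- note(incons, "signals and n_fraction inconsistent")
  }
  if (length(problems))
    stop("assay table validation error:\n  ",
         paste(problems, collapse = "\n  "))

  below <- is_below_detection(sn, s9, detection_limit)
  n_fraction <- ifelse(sig_present,
                       compute_n_fraction(sn, s9, detection_limit), fr)
  data.frame(
    gene_id = as.character(df$gene_id),
    pathway = if ("pathway" %in% names(df)) as.character(df$pathway)
              else NA_character_,
    individual_id = as.character(df$individual_id),
    group = as.character(df$group),
    tissue = as.character(df$tissue),
    stage = unname(tissue_stage[as.character(df$tissue)]),
    signal_N = sn,
    signal_9 = s9,
    n_fraction = n_fraction,
    below_detection = below,
    stringsAsFactors = FALSE
  )
}

#' Read a sample sheet mapping individuals to plant groups
#'
#' @param path TSV file with columns `individual_id`, `group`.
#' @return data.frame with unique individuals and validated group labels.
#' @export
read_sample_sheet <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "group")
  if (!all(need %in% names(df)))
    stop("sample sheet format error: need columns individual_id, group")
  if (anyDuplicated(df$individual_id))
    stop("sample sheet validation error: duplicated individual_id")
  if (!all(df$group %in% PLANT_GROUPS))
    stop("sample sheet validation error: unknown plant group label")
  df[, need]
}

#' Check that every assay record's individual appears in a sample sheet
#'
#' @param records Assay records (from [read_assay_table()]).
#' @param sheet Sample sheet (from [read_sample_sheet()]).
#' @return Invisibly `TRUE`; stops on a missing individual or a group
#'   mismatch.
#' @export
check_sample_sheet <- function(records, sheet) {
  miss <- setdiff(unique(records$individual_id), sheet$individual_id)
  if (length(miss))
    stop("individuals absent from sample sheet: ",
         paste(miss, collapse = ", "))
  m <- match(records$individual_id, sheet$individual_id)
  bad <- which(records$group != sheet$group[m])
  if (length(bad))
    stop("group labels disagree with sample sheet for: ",
         paste(unique(records$individual_id[bad]), collapse = ", "))
  invisible(TRUE)
}

#' Write a tidy TSV result table
#'
#' All pipeline outputs are long-format, tab-separated, UTF-8, one
#' observation per row; missing values are written as empty fields. Numeric
#' columns are serialized with full double precision so a write/read
#' round-trip reproduces the records exactly.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tidy_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      x <- sprintf("%.17g", out[[j]])
      x[is.na(out[[j]])] <- NA_character_
      out[[j]] <- x
    }
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write assay records in the input TSV dialect
#'
#' @param records Assay records as returned by [read_assay_table()] or
#'   [simulate_assays()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assay_table <- function(records, path) {
  keep <- intersect(
    c("gene_id", "pathway", "individual_id", "group", "tissue", "stage",
      "signal_N", "signal_9", "n_fraction"),
    names(records))
  write_tidy_tsv(records[, keep], path)
}
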