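# Calibration QC: each gene's allelotyping assay is validated against
# genomic DNA of the two parents mixed in known ratios (1:3, 1:2, 1:1, 2:1,
# 3:1). A genome-specific assay must recover the expected N-fraction; assays
# are kept when the squared correlation between observed and expected
# fractions exceeds a threshold (default 0.9, strict inequality).

#' Expected N-fraction of a known DNA mix ratio
#'
#' @param ratio_n,ratio_9 Positive parts of the N:9 mix ratio (e.g. 1 and 3
#'   for a 1:3 mix).
#' @return Percentage `ratio_n / (ratio_n + ratio_9) * 100`.
#' @export
#' @examples
#' expected_fraction_from_ratio(1, 3)  # 25
#' expected_fraction_from_ratio(3, 1)  # 75
expected_fraction_from_ratio <- function(ratio_n, ratio_9) {
  stopifnot(is.numeric(ratio_n), is.numeric(ratio_9))
  if (any(!is.finite(ratio_n)) || any(!is.finite(ratio_9)) ||
      any(ratio_n <= 0) || any(ratio_9 <= 0))
    stop("mix ratio parts must be positive and finite")
  ratio_n / (ratio_n + ratio_9) * 100
}

#' Read a calibration table of known-ratio DNA mixes
#'
#' @param path TSV with columns `gene_id`, `ratio_n`, `ratio_9`,
#'   `observed_fraction`.
#' @return data.frame of calibration points with an `expected_fraction`
#'   column added.
#' @export
read_calibration_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "ratio_n", "ratio_9", "observed_fraction")
  if (!all(need %in% names(df)))
    stop("calibration table format error: need columns ",
         paste(need, collapse = ", "))
  if (any(df$observed_fraction < 0 | df$observed_fraction > 100))
    stop("observed_fraction outside [0, 100]")
  df$expected_fraction <- expected_fraction_from_ratio(df$ratio_n, df$ratio_9)
  df
}

#' Fit one gene's calibration line
#'
#' Ordinary least squares of observed on expected N-fraction; the reported
#' R-squared is the squared Pearson correlation (identical to the regression
#' R-squared for a simple linear fit). The assay passes when
#' `r_squared > threshold` (strict).
#'
#' @param points data.frame of calibration points for one gene, with columns
#'   `expected_fraction` and `observed_fraction` (and optionally `gene_id`).
#' @param threshold Pass threshold on R-squared (default 0.9).
#' @return One-row data.frame: `gene_id`, `slope`, `intercept`, `r_squared`,
#'   `n_points`, `passed`.
#' @export
fit_calibration <- function(points, threshold = 0.9) {
  stopifnot(is.data.frame(points),
            all(c("expected_fraction", "observed_fraction") %in%
                  names(points)))
  x <- points$expected_fraction
  y <- points$observed_fraction
  if (length(x) < 2L)
    stop("insufficient data: need at least 2 calibration points")
  if (length(unique(x)) < 2L)
    stop("degenerate design: all expected fractions identical")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  data.frame(
    gene_id = if ("gene_id" %in% names(points))
      as.character(points$gene_id[1L]) else NA_character_,
    slope = unname(co[2L]),
    intercept = unname(co[1L]),
    r_squared = r2,
    n_points = length(x),
    passed = r2 > threshold,
    stringsAsFactors = FALSE
  )
}

#' Fit calibration lines for every gene in a calibration table
#'
#' @param points Calibration points for any number of genes (see
#'   [read_calibration_table()]).
#' @param threshold Pass threshold on R-squared (default 0.9, strict).
#' @return data.frame with one row per gene (see [fit_calibration()]).
#' @export
calibrate_assays <- function(points, threshold = 0.9) {
  stopifnot("gene_id" %in% names(points))
  parts <- split(points, points$gene_id)
  out <- do.call(rbind, lapply(parts, fit_calibration, threshold = threshold))
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Filter assay records to calibration-passing genes
#'
#' @param calibration Calibration results from [calibrate_assays()].
#' @param records Assay records.
#' @param strict If `TRUE` (default), a gene in `records` without a
#'   calibration result is an error; if `FALSE` such genes are dropped with
#'   a warning.
#' @return Records for passing genes only, with attribute `failed_genes`
#'   (genes that failed QC) for reporting.
#' @export
filter_assays <- function(calibration, records, strict = TRUE) {
  genes <- unique(records$gene_id)
  uncal <- setdiff(genes, calibration$gene_id)
  if (length(uncal)) {
    if (strict)
      stop("gene(s) without calibration: ", paste(uncal, collapse = ", "))
    warning("dropping uncalibrated gene(s): ", paste(uncal, collapse = ", "))
  }
  passed <- calibration$gene_id[calibration$passed]
  failed <- setdiff(intersect(genes, calibration$gene_id), passed)
  out <- records[records$gene_id %in% passed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failed_genes") <- failed
  if (length(failed))
    message(length(failed), " gene(s) failed calibration QC: ",
            paste(failed, collapse = ", "))
  out
}
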