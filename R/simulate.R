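# Ground-truthed generator emulating the study design: 30 genes from eight
# key pathways, assayed in six tissues across two growth stages, in four
# plant groups (parental RNA mix, reciprocal F1 hybrids pooled, and the two
# reciprocal synthetic tetraploids). Silencing is drawn per gene x individual
# x tissue x homeolog at group- and tissue-class-specific rates, with
# optional nonfunctionalization (a homeolog off in every tissue) and
# reciprocal-TSS injection; observed fractions get bounded Beta noise.

PATHWAY_LABELS <- c("CP", "CR", "HK", "IP", "Chl", "PS", "N", "TCA")
TISSUE_CLASSES <- c("leaf", "root", "flag", "spike")

default_silencing_prob <- function(p = 0.1) {
  m <- matrix(p, nrow = 4, ncol = 4,
              dimnames = list(c("MIX", "F1", "NN99", "99NN"),
                              TISSUE_CLASSES))
  list(N = m, `9` = m)
}

#' Build a simulation configuration
#'
#' @param n_genes Number of genes (default 30, as in the assayed panel).
#' @param group_sizes Named integer vector of individuals per plant group
#'   (default `c(MIX = 6, F1 = 6, NN99 = 7, "99NN" = 7)`).
#' @param silencing_prob Either a single probability, a groups x
#'   tissue-classes matrix (rows `MIX`, `F1`, `NN99`, `99NN`; columns
#'   `leaf`, `root`, `flag`, `spike`), or a list with such a matrix per
#'   homeolog (`N`, `9`). Probability that a homeolog is silenced in a
#'   tissue, per gene and individual.
#' @param nonfunc_prob Named-by-group (or scalar) probability that a
#'   homeolog is silenced in all tissues of a gene x individual.
#' @param reciprocal_prob Named-by-group (or scalar) probability of
#'   injecting a reciprocal-TSS pattern (N silenced in one random tissue, 9
#'   in another) per gene x individual.
#' @param bias_attenuation Named-by-group (or scalar) shrinkage in `[0, 1]`
#'   of each gene's baseline N-fraction toward 50%: 1 leaves the parental
#'   difference intact (the in vitro mix), smaller values emulate
#'   trans-regulator equalization in hybrids.
#' @param baseline_mean,baseline_concentration Mean (percent) and
#'   concentration of the Beta distribution of per-gene baseline
#'   N-fractions.
#' @param noise_concentration Precision of the Beta measurement noise on
#'   fractions; `Inf` disables noise.
#' @param silent_leak Percent signal leaking through a silenced homeolog
#'   (default 1): single-homeolog silencing emits a true fraction of
#'   `silent_leak` or `100 - silent_leak` rather than exactly 0/100.
#' @param detection_dropout Probability a measurement is missing.
#' @param total_intensity_meanlog,total_intensity_sdlog Log-normal
#'   parameters of the total signal intensity (arbitrary units).
#' @param deterministic_reciprocal Optional integer `k`: instead of random
#'   injection, place exactly `k` reciprocal patterns (N silenced in `L2`,
#'   9 in `R2`) into the first `k` gene x individual slots.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_genes = 30,
                              group_sizes = c(MIX = 6, F1 = 6, NN99 = 7,
                                              `99NN` = 7),
                              silencing_prob = 0.1,
                              nonfunc_prob = 0,
                              reciprocal_prob = 0,
                              bias_attenuation = 1,
                              baseline_mean = 50,
                              baseline_concentration = 4.5,
                              noise_concentration = 300,
                              silent_leak = 1,
                              detection_dropout = 0,
                              total_intensity_meanlog = log(1000),
                              total_intensity_sdlog = 0.4,
                              deterministic_reciprocal = NULL,
                              seed = 1) {
  groups <- names(group_sizes)
  stopifnot(n_genes >= 1, all(group_sizes >= 1), !is.null(groups))
  expand_by_group <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(x, length(groups)), groups)
    if (!all(groups %in% names(x)))
      stop("config error: ", what, " must cover all groups")
    x <- x[groups]
    if (any(x < 0 | x > 1)) stop("config error: ", what, " outside [0, 1]")
    x
  }
  if (is.numeric(silencing_prob) && length(silencing_prob) == 1L) {
    if (silencing_prob < 0 || silencing_prob > 1)
      stop("config error: silencing_prob outside [0, 1]")
    silencing_prob <- default_silencing_prob(silencing_prob)
    silencing_prob$N <- silencing_prob$N[groups, , drop = FALSE]
    silencing_prob$`9` <- silencing_prob$`9`[groups, , drop = FALSE]
  } else if (is.matrix(silencing_prob)) {
    silencing_prob <- list(N = silencing_prob, `9` = silencing_prob)
  }
  for (h in c("N", "9")) {
    m <- silencing_prob[[h]]
    if (!all(groups %in% rownames(m)) ||
        !all(TISSUE_CLASSES %in% colnames(m)))
      stop("config error: silencing_prob matrix needs rows ",
           paste(groups, collapse = ","), " and columns ",
           paste(TISSUE_CLASSES, collapse = ","))
    if (any(m < 0 | m > 1))
      stop("config error: silencing_prob outside [0, 1]")
    silencing_prob[[h]] <- m[groups, TISSUE_CLASSES, drop = FALSE]
  }
  stopifnot(baseline_mean > 0, baseline_mean < 100,
            baseline_concentration > 0, noise_concentration > 0,
            silent_leak >= 0, silent_leak < 50,
            detection_dropout >= 0, detection_dropout <= 1)
  structure(list(
    n_genes = as.integer(n_genes),
    group_sizes = group_sizes,
    groups = groups,
    silencing_prob = silencing_prob,
    nonfunc_prob = expand_by_group(nonfunc_prob, "nonfunc_prob"),
    reciprocal_prob = expand_by_group(reciprocal_prob, "reciprocal_prob"),
    bias_attenuation = expand_by_group(bias_attenuation, "bias_attenuation"),
    baseline_mean = baseline_mean,
    baseline_concentration = baseline_concentration,
    noise_concentration = noise_concentration,
    silent_leak = silent_leak,
    detection_dropout = detection_dropout,
    total_intensity_meanlog = total_intensity_meanlog,
    total_intensity_sdlog = total_intensity_sdlog,
    deterministic_reciprocal = deterministic_reciprocal,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Study-like simulation preset
#'
#' Configuration emulating the study's qualitative findings: the parental
#' RNA mix has the highest silencing rates (pre-existing expression
#' differences between the two cultivars), F1 hybrids the lowest
#' (trans-regulator equalization), the synthetic tetraploids intermediate
#' with 99NN above NN99, and roots silenced far more often than leaves.
#' Baseline biases are broad for the mix (attenuation 1) and shrunk toward
#' 50% in the F1, so most mix loci show unequal allelic expression while
#' most F1 loci are equivalent. Reciprocal-TSS rates in the tetraploids are
#' set so a full dataset carries on the order of a dozen reciprocal cases.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
paper_like_config <- function(seed = 1, ...) {
  sil <- function(leaf, root, flag, spike) c(leaf, root, flag, spike)
  m <- rbind(MIX = sil(0.10, 0.22, 0.08, 0.08),
             F1 = sil(0.01, 0.03, 0.01, 0.01),
             NN99 = sil(0.04, 0.16, 0.06, 0.06),
             `99NN` = sil(0.06, 0.22, 0.08, 0.08))
  colnames(m) <- TISSUE_CLASSES
  defaults <- list(
    n_genes = 30,
    group_sizes = c(MIX = 6, F1 = 6, NN99 = 7, `99NN` = 7),
    silencing_prob = m,
    nonfunc_prob = c(MIX = 0.01, F1 = 0.002, NN99 = 0.01, `99NN` = 0.015),
    reciprocal_prob = c(MIX = 0.02, F1 = 0.003, NN99 = 0.03, `99NN` = 0.035),
    bias_attenuation = c(MIX = 1, F1 = 0.3, NN99 = 0.6, `99NN` = 0.75),
    baseline_mean = 50, baseline_concentration = 4.5,
    noise_concentration = 300, silent_leak = 1, detection_dropout = 0,
    seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Simulate a homeolog assay dataset with ground truth
#'
#' Draws true silencing states per gene x individual x tissue x homeolog
#' (baseline rates plus nonfunctionalization and reciprocal-TSS injection),
#' converts them to true N-fractions (a silenced homeolog leaks
#' `silent_leak` percent; both silenced gives a no-expression measurement),
#' applies Beta measurement noise and dropout, and emits signal intensities.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return List of class `tss_simulation`: `records` (an assay table as from
#'   [read_assay_table()]), `truth` (one row per gene x individual x tissue
#'   with logical `silenced_N`, `silenced_9` and the pre-noise
#'   `true_fraction`), and `config`.
#' @export
simulate_assays <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  pw <- PATHWAY_LABELS[((seq_len(G) - 1L) %% length(PATHWAY_LABELS)) + 1L]
  gene_ids <- paste0(pw, "_", seq_len(G))
  groups_of_ind <- rep(config$groups, config$group_sizes)
  ind_ids <- unlist(lapply(seq_along(config$groups), function(i)
    paste0(config$groups[i], "_", seq_len(config$group_sizes[i]))),
    use.names = FALSE)
  nI <- length(ind_ids)
  nT <- length(TISSUES)

  m0 <- config$baseline_mean / 100
  c0 <- config$baseline_concentration
  base <- stats::rbeta(G, m0 * c0, (1 - m0) * c0) * 100

  # gene x individual slots (gene fastest)
  slot_gene <- rep(seq_len(G), times = nI)
  slot_ind <- rep(seq_len(nI), each = G)
  slot_group <- groups_of_ind[slot_ind]
  nS <- length(slot_gene)

  nfN <- stats::rbinom(nS, 1L, config$nonfunc_prob[slot_group]) == 1L
  nf9 <- stats::rbinom(nS, 1L, config$nonfunc_prob[slot_group]) == 1L
  if (!is.null(config$deterministic_reciprocal)) {
    k <- config$deterministic_reciprocal
    stopifnot(k >= 0, k <= nS)
    rec <- seq_len(nS) <= k
    rec_tN <- rep(match("L2", TISSUES), nS)
    rec_t9 <- rep(match("R2", TISSUES), nS)
  } else {
    rec <- stats::rbinom(nS, 1L, config$reciprocal_prob[slot_group]) == 1L
    rec_tN <- sample.int(nT, nS, replace = TRUE)
    rec_t9 <- ((rec_tN - 1L + sample.int(nT - 1L, nS, replace = TRUE)) %%
                 nT) + 1L
  }

  # full record grid (tissue fastest within slot)
  r_slot <- rep(seq_len(nS), each = nT)
  r_tissue <- rep(seq_len(nT), times = nS)
  cls <- TISSUE_CLASS[TISSUES[r_tissue]]
  grp <- slot_group[r_slot]
  pN <- config$silencing_prob$N[cbind(grp, cls)]
  p9 <- config$silencing_prob$`9`[cbind(grp, cls)]
  nR <- length(r_slot)
  sN <- stats::rbinom(nR, 1L, pN) == 1L
  s9 <- stats::rbinom(nR, 1L, p9) == 1L
  sN <- sN | nfN[r_slot] | (rec[r_slot] & r_tissue == rec_tN[r_slot])
  s9 <- s9 | nf9[r_slot] | (rec[r_slot] & r_tissue == rec_t9[r_slot])

  att <- config$bias_attenuation[grp]
  base_att <- 50 + att * (base[slot_gene[r_slot]] - 50)
  eps <- config$silent_leak
  true_frac <- ifelse(sN & s9, NA_real_,
                      ifelse(sN, eps, ifelse(s9, 100 - eps, base_att)))

  cc <- config$noise_concentration
  obs_frac <- true_frac
  if (is.finite(cc)) {
    ok <- !is.na(true_frac)
    mu <- true_frac[ok] / 100
    obs_frac[ok] <- stats::rbeta(sum(ok), mu * cc, (1 - mu) * cc) * 100
  }
  total <- stats::rlnorm(nR, config$total_intensity_meanlog,
                         config$total_intensity_sdlog)
  signal_N <- ifelse(is.na(obs_frac), 0, total * obs_frac / 100)
  signal_9 <- ifelse(is.na(obs_frac), 0, total * (100 - obs_frac) / 100)

  records <- data.frame(
    gene_id = gene_ids[slot_gene[r_slot]],
    pathway = pw[slot_gene[r_slot]],
    individual_id = ind_ids[slot_ind[r_slot]],
    group = grp,
    tissue = TISSUES[r_tissue],
    stage = unname(TISSUE_STAGE[TISSUES[r_tissue]]),
    signal_N = signal_N,
    signal_9 = signal_9,
    n_fraction = obs_frac,
    below_detection = is.na(obs_frac),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    gene_id = records$gene_id,
    individual_id = records$individual_id,
    group = records$group,
    tissue = records$tissue,
    silenced_N = sN,
    silenced_9 = s9,
    true_fraction = true_frac,
    stringsAsFactors = FALSE
  )
  if (config$detection_dropout > 0) {
    drop <- stats::runif(nR) < config$detection_dropout
    records <- records[!drop, , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(records = records, truth = truth, config = config),
            class = "tss_simulation")
}

#' @export
print.tss_simulation <- function(x, ...) {
  cat("Simulated homeolog assay dataset:", nrow(x$records), "records,",
      x$config$n_genes, "genes,", sum(x$config$group_sizes),
      "individuals (seed", x$config$seed, ")\n")
  invisible(x)
}

# P(observed fraction < 5% | true mean mu on [0,1]) under Beta noise with
# concentration cc; and the >= 95% analogue. cc = Inf degenerates to the
# indicator of the true value.
.p_call_low <- function(mu, cc) {
  if (is.finite(cc)) stats::pbeta(0.05, mu * cc, (1 - mu) * cc)
  else as.numeric(mu < 0.05)
}
.p_call_high <- function(mu, cc) {
  if (is.finite(cc)) stats::pbeta(0.95, mu * cc, (1 - mu) * cc,
                                  lower.tail = FALSE)
  else as.numeric(mu >= 0.95)
}

#' Analytic expected TSS percentage under a simulation configuration
#'
#' Closed-form expectation of the per-individual TSS percentage (default
#' denominator, see [score_tss()]) for one plant group over a tissue set,
#' under the generator's model: exact enumeration over the
#' nonfunctionalization and reciprocal-injection modes and the per-tissue
#' silencing states, with Beta-noise misclassification probabilities
#' integrated over the gene-baseline distribution on an equal-probability
#' quantile grid. Used as the nominal value in parameter-recovery checks;
#' it shares no code with the detection path.
#'
#' Assumes the complete design (`detection_dropout = 0`); a warning is
#' issued otherwise since the denominator is then random.
#'
#' @param config A `sim_config`.
#' @param group Plant group name.
#' @param tissue_set Character vector of tissues (see [tissue_sets()]).
#' @param n_grid Size of the baseline quantile grid (default 401).
#' @return Expected TSS percentage (scalar).
#' @export
expected_tss_percent <- function(config, group, tissue_set, n_grid = 401L) {
  stopifnot(inherits(config, "sim_config"), group %in% config$groups)
  if (config$detection_dropout > 0)
    warning("expected_tss_percent assumes detection_dropout = 0")
  K <- tissue_set
  k <- length(K)
  cls <- TISSUE_CLASS[K]
  pN0 <- config$silencing_prob$N[group, cls]
  p90 <- config$silencing_prob$`9`[group, cls]
  nu <- config$nonfunc_prob[[group]]
  rho <- if (!is.null(config$deterministic_reciprocal)) 0
         else config$reciprocal_prob[[group]]
  cc <- config$noise_concentration
  eps <- config$silent_leak / 100
  att <- config$bias_attenuation[[group]]
  m0 <- config$baseline_mean / 100
  c0 <- config$baseline_concentration

  q <- stats::qbeta((seq_len(n_grid) - 0.5) / n_grid, m0 * c0, (1 - m0) * c0)
  mu_b <- 0.5 + att * (q - 0.5)           # attenuated baseline, [0,1] scale
  Flo_b <- .p_call_low(mu_b, cc)          # expressed record called N-silenced
  Fhi_b <- .p_call_high(mu_b, cc)         # expressed record called 9-silenced
  Flo_eps <- .p_call_low(eps, cc)         # N truly silenced, called silenced
  Fhi_eps <- .p_call_high(eps, cc)        # N truly silenced, called 9-silenced
  Flo_hi <- .p_call_low(1 - eps, cc)
  Fhi_hi <- .p_call_high(1 - eps, cc)

  # expected numerator for one homeolog, given per-tissue override-adjusted
  # silencing probs (vectors over K); all quantities vectors over the grid
  num_one <- function(pN, p9, target_n) {
    sil <- vector("list", k); expr <- vector("list", k)
    for (t in seq_len(k)) {
      a <- pN[t]; b <- p9[t]
      if (target_n) {
        s <- a * (1 - b) * Flo_eps + (1 - a) * (1 - b) * Flo_b +
          (1 - a) * b * Flo_hi
      } else {
        s <- (1 - a) * b * Fhi_hi + (1 - a) * (1 - b) * Fhi_b +
          a * (1 - b) * Fhi_eps
      }
      sil[[t]] <- s
      expr[[t]] <- 1 - s - a * b
    }
    total <- 0
    for (t in seq_len(k)) {
      none_other <- 1
      for (u in seq_len(k)) if (u != t) none_other <- none_other *
          (1 - expr[[u]])
      total <- total + sil[[t]] * (1 - none_other)
    }
    total
  }

  all_t <- TISSUES
  modes_num <- 0
  for (nfN in c(FALSE, TRUE)) for (nf9 in c(FALSE, TRUE)) {
    w_nf <- (if (nfN) nu else 1 - nu) * (if (nf9) nu else 1 - nu)
    if (w_nf == 0) next
    apply_mode <- function(tN, t9, w_rec) {
      pN <- pN0; p9 <- p90
      if (nfN) pN[] <- 1
      if (nf9) p9[] <- 1
      if (!is.na(tN) && all_t[tN] %in% K) pN[match(all_t[tN], K)] <- 1
      if (!is.na(t9) && all_t[t9] %in% K) p9[match(all_t[t9], K)] <- 1
      w_nf * w_rec * (num_one(pN, p9, TRUE) + num_one(pN, p9, FALSE))
    }
    modes_num <- modes_num + apply_mode(NA, NA, 1 - rho)
    if (rho > 0) {
      w_pair <- rho / (length(all_t) * (length(all_t) - 1L))
      for (tN in seq_along(all_t)) for (t9 in seq_along(all_t)) {
        if (t9 == tN) next
        modes_num <- modes_num + apply_mode(tN, t9, w_pair)
      }
    }
  }
  100 * mean(modes_num) / (2 * k)
}

#' Simulate known-ratio calibration data
#'
#' Generates calibration points for each gene over the standard DNA mix
#' ratios (1:3, 1:2, 1:1, 2:1, 3:1) with Gaussian measurement error on the
#' observed fraction, truncated to `[0, 100]`.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param noise_sd Standard deviation of the observation error in
#'   percentage points (default 2).
#' @param ratios Two-column matrix of mix ratio parts (default the standard
#'   five).
#' @param seed Optional integer seed.
#' @return data.frame of calibration points (see [read_calibration_table()]).
#' @export
simulate_calibration <- function(gene_ids, noise_sd = 2,
                                 ratios = cbind(c(1, 1, 1, 2, 3),
                                                c(3, 2, 1, 1, 1)),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ratios)
  out <- data.frame(
    gene_id = rep(gene_ids, each = n),
    ratio_n = rep(ratios[, 1L], times = length(gene_ids)),
    ratio_9 = rep(ratios[, 2L], times = length(gene_ids)),
    stringsAsFactors = FALSE)
  out$expected_fraction <- expected_fraction_from_ratio(out$ratio_n,
                                                        out$ratio_9)
  obs <- out$expected_fraction + stats::rnorm(nrow(out), 0, noise_sd)
  out$observed_fraction <- pmin(100, pmax(0, obs))
  out
}

# Truth-level "calls" for running the detection definitions on the true
# silencing states: both homeologs silenced is a no-expression tissue.
truth_calls <- function(truth) {
  data.frame(
    gene_id = truth$gene_id,
    individual_id = truth$individual_id,
    group = truth$group,
    tissue = truth$tissue,
    silenced_N = truth$silenced_N & !truth$silenced_9,
    silenced_9 = truth$silenced_9 & !truth$silenced_N,
    category = ifelse(truth$silenced_N & truth$silenced_9,
                      "NO_EXPRESSION", "EXPRESSED_SOMEHOW"),
    stringsAsFactors = FALSE)
}

#' Sensitivity and specificity of silencing calls against ground truth
#'
#' Derives the true TSS and nonfunctionalization events from a simulation's
#' ground-truth silencing states (using the same definitions, applied to
#' truth rather than to noisy calls) and scores the detected events against
#' them per (gene, individual, homeolog, tissue set, kind) slot. With noise
#' and dropout off, detection reproduces truth exactly.
#'
#' @param truth Ground truth from [simulate_assays()].
#' @param events Detected events from [partition_events()] on the same
#'   simulation's classified records.
#' @param sets Named list of tissue sets matching those used for `events`.
#' @return List: `sensitivity`, `specificity`, `tp`, `fp`, `fn`, `tn`, and a
#'   per-kind breakdown `by_kind`.
#' @export
recovery_report <- function(truth, events, sets = tissue_sets()) {
  if (!all(unique(events$individual_id) %in% unique(truth$individual_id)))
    stop("events reference individuals absent from the ground truth")
  tcalls <- truth_calls(truth)
  truth_ev <- partition_events(tcalls, sets = sets)
  keyify <- function(e) {
    e <- e[e$kind %in% c("TSS", "NONFUNCTIONALIZATION") &
             e$tissue_set %in% names(sets), , drop = FALSE]
    paste(e$gene_id, e$individual_id, e$homeolog, e$tissue_set, e$kind,
          sep = "\r")
  }
  pos_true <- unique(keyify(truth_ev))
  pos_det <- unique(keyify(events))
  genes <- unique(truth$gene_id)
  inds <- unique(truth$individual_id)
  universe <- length(genes) * length(inds) * 2L * length(sets) * 2L
  tp <- length(intersect(pos_det, pos_true))
  fp <- length(setdiff(pos_det, pos_true))
  fn <- length(setdiff(pos_true, pos_det))
  tn <- universe - tp - fp - fn
  by_kind <- lapply(c(TSS = "TSS", NONFUNCTIONALIZATION =
                        "NONFUNCTIONALIZATION"), function(kd) {
    pt <- grep(paste0("\r", kd, "$"), pos_true, value = TRUE)
    pd <- grep(paste0("\r", kd, "$"), pos_det, value = TRUE)
    c(tp = length(intersect(pd, pt)), fp = length(setdiff(pd, pt)),
      fn = length(setdiff(pt, pd)))
  })
  list(
    sensitivity = if (length(pos_true)) tp / length(pos_true) else NA_real_,
    specificity = if (universe - length(pos_true) > 0)
      tn / (universe - length(pos_true)) else NA_real_,
    tp = tp, fp = fp, fn = fn, tn = tn,
    by_kind = by_kind)
}
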