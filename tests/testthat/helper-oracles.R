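# Independent oracles, deliberately coded from the definitions rather than
# sharing any implementation with the package.

# R-squared by raw normal-equation sums.
oracle_r2 <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  if (syy == 0) return(0)
  sxy^2 / (sxx * syy)
}

# Exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1) group
# labelings of the pooled tie-free sample.
oracle_mw_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(length(pool), n1)
  u_all <- apply(picks, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^k sign
# assignments to the nonzero differences.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  k <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  v_all <- as.vector(signs %*% r)
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Brute-force TSS/nonfunctionalization/reciprocal detection straight from
# the category definitions, for one gene x individual over measured tissues.
# Returns a character vector of "homeolog:kind" strings.
brute_detect <- function(categories, tissues) {
  out <- character(0)
  got_tss <- c(N = FALSE, `9` = FALSE)
  for (h in c("N", "9")) {
    silenced_cat <- if (h == "N") "COMPLETE_9" else "COMPLETE_N"
    sil <- categories == silenced_cat
    expr <- categories != silenced_cat & categories != "NO_EXPRESSION"
    if (all(sil)) {
      out <- c(out, paste0(h, ":NONFUNCTIONALIZATION"))
    } else if (any(sil) && any(expr)) {
      out <- c(out, paste0(h, ":TSS"))
      got_tss[h] <- TRUE
    }
  }
  if (all(got_tss)) out <- c(out, "NA:RECIPROCAL_TSS")
  sort(out)
}

# Build a classified-calls data.frame from per-tissue categories.
make_calls <- function(gene, ind, tissues, categories, group = "MIX") {
  df <- data.frame(gene_id = gene, individual_id = ind, group = group,
                   tissue = tissues,
                   category = factor(categories, levels = bias_levels()),
                   stringsAsFactors = FALSE)
  cbind(df, call_silencing(df$category))
}
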