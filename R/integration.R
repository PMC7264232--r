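# Cross-referencing MPRA calls with eQTL direction, Taqman allele-specific
# expression, and allelic-proteomics outliers.

#' Direction consistency between MPRA allelic effect and eQTL slope
#'
#' Harmonises the eQTL slope to the risk allele (negated when the stored
#' effect allele is the protective one) and compares signs with the MPRA
#' allelic effect: `"consistent"` when the risk allele drives expression and
#' reporter activity in the same direction, `"inconsistent"` otherwise, and
#' `"not_applicable"` when either result is non-significant.
#'
#' @param beta_allele MPRA allelic effect(s), log2 scale, risk minus
#'   protective.
#' @param mpra_significant logical; the MPRA call's significance flag.
#' @param slope eQTL slope(s), expression change per copy of `effect_allele`.
#' @param eqtl_significant logical; eQTL significance at its gene-level
#'   threshold.
#' @param effect_allele,risk_allele,protective_allele allele strings used for
#'   harmonisation; `effect_allele` must match one of the other two.
#' @return character vector in
#'   `{consistent, inconsistent, not_applicable}`.
#' @export
direction_consistency <- function(beta_allele, mpra_significant, slope,
                                  eqtl_significant, effect_allele,
                                  risk_allele, protective_allele) {
  n <- length(beta_allele)
  is_risk <- effect_allele == risk_allele
  is_prot <- effect_allele == protective_allele
  bad <- !is_risk & !is_prot
  if (any(bad)) {
    stop("effect_allele matches neither the risk nor the protective allele",
         call. = FALSE)
  }
  harmonised <- ifelse(is_risk, slope, -slope)
  out <- rep("not_applicable", n)
  applicable <- isTRUE_v(mpra_significant) & isTRUE_v(eqtl_significant)
  agree <- sign(beta_allele) == sign(harmonised)
  out[applicable] <- ifelse(agree[applicable], "consistent", "inconsistent")
  out
}

#' Normalised allelic expression ratio from qPCR triplicates
#'
#' The per-material allelic ratio is `2^-(mean(Ct_A - Ct_C))` over the
#' triplicates; the cDNA ratio is normalised to the genomic-DNA ratio to
#' remove assay and copy-number bias.
#'
#' @param ct_a_cdna,ct_c_cdna,ct_a_gdna,ct_c_gdna numeric Ct triplicates for
#'   each allele in cDNA and genomic DNA.
#' @return the normalised A/C ratio (scalar).
#' @export
ase_ratio <- function(ct_a_cdna, ct_c_cdna, ct_a_gdna, ct_c_gdna) {
  r_cdna <- 2^(-mean(ct_a_cdna - ct_c_cdna))
  r_gdna <- 2^(-mean(ct_a_gdna - ct_c_gdna))
  r_cdna / r_gdna
}

#' Per-sample allele-specific-expression ratios with QC
#'
#' Applies the QC rule (every Ct below `ct_max` in both materials, sample
#' heterozygous) and computes the normalised ratio per sample.
#'
#' @param ase tibble with one row per sample: `sample_id`, `heterozygous`,
#'   and triplicate columns `ct_a_cdna_1..3`, `ct_c_cdna_1..3`,
#'   `ct_a_gdna_1..3`, `ct_c_gdna_1..3`.
#' @param ct_max QC ceiling on every Ct value.
#' @return tibble with `sample_id`, `qc_pass`, and `ratio` (`NA` for QC
#'   failures).
#' @export
ase_ratios <- function(ase, ct_max = 38) {
  tri <- function(prefix) {
    as.matrix(ase[, paste0(prefix, "_", 1:3)])
  }
  a_c <- tri("ct_a_cdna"); c_c <- tri("ct_c_cdna")
  a_g <- tri("ct_a_gdna"); c_g <- tri("ct_c_gdna")
  all_ct <- cbind(a_c, c_c, a_g, c_g)
  qc <- apply(all_ct < ct_max, 1L, all) & isTRUE_v(ase$heterozygous)
  ratio <- 2^(-(rowMeans(a_c - c_c))) / 2^(-(rowMeans(a_g - c_g)))
  tibble(sample_id = ase$sample_id, qc_pass = qc,
         ratio = ifelse(qc, ratio, NA_real_))
}

# One-sample signed-rank statistic with Pratt handling of exact zeros:
# zeros are ranked together with the non-zero differences but contribute
# nothing to the statistic; normal approximation with continuity correction.
signed_rank_pratt <- function(d) {
  r <- rank(abs(d))
  nz <- d != 0
  w_pos <- sum(r[nz & d > 0])
  w_neg <- sum(r[nz & d < 0])
  n <- length(d)
  n0 <- sum(!nz)
  mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  ties <- table(r)
  sigma2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

#' One-sample Wilcoxon test of allelic-expression ratios against 1
#'
#' Tests whether the normalised allelic ratios across heterozygous samples
#' depart from equality, by a two-sided one-sample Wilcoxon signed-rank test
#' of the log ratios against zero (default) or of the raw ratios against 1.
#' The exact signed-rank distribution is used up to n = 50 when there are no
#' ties or zeros; otherwise a normal approximation with continuity
#' correction is used, with Pratt handling of exact zeros.
#'
#' @param ratios numeric vector of normalised ratios (`NA` dropped).
#' @param scale `"log"` (test log ratio vs 0) or `"linear"` (ratio vs 1).
#' @return list with `p_value`, `n`, `statistic`, `method`.
#' @export
ase_test <- function(ratios, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 5L) stop("need at least 5 ratios", call. = FALSE)
  d <- if (scale == "log") log(ratios) else ratios - 1
  if (all(d == 0)) {
    warning("all ratios exactly 1; test degenerate")
    return(list(p_value = 1, n = length(d), statistic = NA_real_,
                method = "degenerate"))
  }
  if (any(d == 0) || any(duplicated(abs(d)))) {
    p <- signed_rank_pratt(d)
    return(list(p_value = p, n = length(d),
                statistic = sum(rank(abs(d))[d > 0]),
                method = "normal approximation (Pratt zeros, ties mid-ranked)"))
  }
  wt <- wilcox.test(d, mu = 0, exact = length(d) <= 50L, correct = TRUE)
  list(p_value = wt$p.value, n = length(d),
       statistic = unname(wt$statistic),
       method = if (length(d) <= 50L) "exact signed-rank" else
         "normal approximation with continuity correction")
}

#' Call allelically bound proteins from label-swapped mass-spec ratios
#'
#' Each protein carries two log ratios from label-swapped replicate
#' pulldowns: the A-bound/C-bound axis and the C-bound/A-bound axis. Both
#' axes are shifted to median zero, and a protein is called an allelic
#' binder when it lies beyond `k` interquartile ranges outside the quartiles
#' on **both** axes in the label-swap-consistent directions (A-preferential:
#' high on the first axis, low on the second; C-preferential: the reverse).
#' Double outliers with label-swap-inconsistent directions are flagged
#' separately.
#'
#' @param ms tibble with `protein_id`, `log_ratio_rep1` (A/C axis) and
#'   `log_ratio_rep2` (C/A axis); non-finite ratios are dropped with a count.
#' @param k IQR multiplier for the outlier fence.
#' @param quantile_type quartile convention passed to [stats::quantile()].
#' @return tibble with `protein_id`, centred ratios, and `class` in
#'   `{none, A_preferential, C_preferential, inconsistent}`; fences are
#'   attached as attribute `"fences"`, the dropped-row count as
#'   `"n_dropped"`.
#' @export
ms_outlier_call <- function(ms, k = 1.5, quantile_type = 7L) {
  fin <- is.finite(ms$log_ratio_rep1) & is.finite(ms$log_ratio_rep2)
  n_dropped <- sum(!fin)
  ms <- ms[fin, , drop = FALSE]
  if (nrow(ms) < 8L) {
    stop("need >= 8 proteins with finite ratios for stable quartiles",
         call. = FALSE)
  }
  x <- ms$log_ratio_rep1 - median(ms$log_ratio_rep1)
  y <- ms$log_ratio_rep2 - median(ms$log_ratio_rep2)
  fence <- function(v) {
    q <- quantile(v, c(0.25, 0.75), type = quantile_type, names = FALSE)
    c(lo = q[1] - k * (q[2] - q[1]), hi = q[2] + k * (q[2] - q[1]))
  }
  fx <- fence(x)
  fy <- fence(y)
  cls <- rep("none", nrow(ms))
  cls[x > fx["hi"] & y < fy["lo"]] <- "A_preferential"
  cls[x < fx["lo"] & y > fy["hi"]] <- "C_preferential"
  cls[(x > fx["hi"] & y > fy["hi"]) | (x < fx["lo"] & y < fy["lo"])] <-
    "inconsistent"
  out <- tibble(protein_id = ms$protein_id, centred_rep1 = x,
                centred_rep2 = y, class = cls)
  attr(out, "fences") <- list(rep1 = fx, rep2 = fy)
  attr(out, "n_dropped") <- n_dropped
  out
}
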