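# Per-variant allelic activity statistics: OLS with heteroskedasticity-
# consistent sandwich covariance, robust Wald tests against the paired allele
# and against the scrambled null, BH FDR, and dual-criteria calling.

# ---- OLS + sandwich core ---------------------------------------------------

# Greedy deterministic pruning of collinear columns: columns are visited in
# order and kept only if they increase the rank, so among interchangeable
# dummies the earliest (lexicographically first level) survives.
drop_collinear <- function(X, tol = 1e-8) {
  qx <- qr(X, tol = tol)
  if (qx$rank == ncol(X)) return(list(X = X, dropped = character(0)))
  keep <- logical(ncol(X))
  r <- 0L
  for (j in seq_len(ncol(X))) {
    cand <- X[, c(which(keep), j), drop = FALSE]
    if (qr(cand, tol = tol)$rank > r) {
      keep[j] <- TRUE
      r <- r + 1L
    }
  }
  list(X = X[, keep, drop = FALSE], dropped = colnames(X)[!keep])
}

# OLS fit with HC0-HC3 sandwich covariance, via QR.  X must be full rank.
ols_sandwich <- function(X, y, hc_type = "HC3") {
  n <- nrow(X)
  p <- ncol(X)
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  e <- as.numeric(y - X %*% beta)
  Q <- qr.Q(qx)
  h <- rowSums(Q^2)
  sigma2 <- sum(e^2) / (n - p)
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  # leverage ~ 1 means a point fit exactly; its residual carries no
  # information and the HC2/HC3 weight would blow up
  hsafe <- pmin(h, 1 - 1e-10)
  w <- switch(hc_type,
    HC0 = e^2,
    HC1 = e^2 * n / (n - p),
    HC2 = e^2 / (1 - hsafe),
    HC3 = e^2 / (1 - hsafe)^2,
    stop("hc_type must be one of HC0-HC3", call. = FALSE)
  )
  meat <- crossprod(X, X * w)
  V <- xtx_inv %*% meat %*% xtx_inv
  V <- (V + t(V)) / 2
  list(coefficients = beta, residuals = e, leverages = h,
       ols_cov = sigma2 * xtx_inv, robust_cov = V, n_obs = n, rank = p)
}

# Design matrix: intercept, focal 0/1 predictor, strand, transfection dummies
# (levels sorted, first as reference).  Constant columns are dropped before
# the rank check so single-strand or single-transfection data still fit.
activity_design <- function(predictor, orientation, transfection) {
  X <- cbind("(Intercept)" = 1, predictor = as.numeric(predictor))
  strand <- as.numeric(orientation == "reverse")
  if (length(unique(strand)) > 1L) X <- cbind(X, strand_reverse = strand)
  lev <- sort(unique(as.character(transfection)))
  if (length(lev) > 1L) {
    for (l in lev[-1L]) {
      X <- cbind(X, as.numeric(transfection == l))
      colnames(X)[ncol(X)] <- paste0("transfection_", l)
    }
  }
  X
}

robust_wald <- function(obs, predictor, hc_type, term = "predictor") {
  X <- activity_design(predictor, obs$orientation, obs$transfection_id)
  pruned <- drop_collinear(X)
  if (term %in% pruned$dropped || nrow(pruned$X) < ncol(pruned$X) + 1L) {
    return(list(fit = NULL, beta = NA_real_, se = NA_real_, z = NA_real_,
                p = NA_real_, dropped = pruned$dropped,
                reason = if (term %in% pruned$dropped) {
                  "focal predictor collinear"
                } else "fewer observations than rank + 1"))
  }
  fit <- ols_sandwich(pruned$X, obs$log2_ratio, hc_type)
  fit$dropped_columns <- pruned$dropped
  beta <- unname(fit$coefficients[term])
  se <- sqrt(fit$robust_cov[term, term])
  z <- beta / se
  list(fit = fit, beta = beta, se = se, z = z,
       p = 2 * pnorm(-abs(z)), dropped = pruned$dropped, reason = NA_character_)
}

#' Allelic activity regression for one variant
#'
#' Ordinary least squares of the per-tag log2(RNA/DNA TPM) ratio on allele
#' (risk = 1, protective = 0), adjusting for strand (reverse = 1) and
#' transfection as a categorical covariate; inference uses a
#' heteroskedasticity-consistent sandwich covariance (HC3 by default, the
#' small-sample recommendation) and a two-sided Wald test against the
#' standard normal. Each retained tag-by-transfection ratio is an
#' experimental replicate. Scrambled observations are ignored here.
#'
#' @param obs observation tibble for one variant with columns `log2_ratio`,
#'   `seq_class`, `orientation`, `transfection_id`.
#' @param hc_type sandwich flavour, one of `"HC0"`-`"HC3"`.
#' @return an object of class `allelic_fit`: the full regression fit
#'   (coefficients, residuals, leverages, OLS and robust covariances, dropped
#'   columns) plus `beta_allele`, `se`, `z`, `p`.
#' @export
fit_allelic_regression <- function(obs, hc_type = "HC3") {
  obs <- obs[obs$seq_class %in% c("risk", "protective"), , drop = FALSE]
  tab <- table(obs$seq_class)
  if (length(tab) < 2L || any(tab[c("risk", "protective")] < 2L)) {
    return(structure(list(beta_allele = NA_real_, se = NA_real_,
                          z = NA_real_, p = NA_real_, fit = NULL,
                          reason = "need >= 2 observations per allele"),
                     class = "allelic_fit"))
  }
  w <- robust_wald(obs, obs$seq_class == "risk", hc_type)
  structure(list(beta_allele = w$beta, se = w$se, z = w$z, p = w$p,
                 fit = w$fit, dropped_columns = w$dropped, reason = w$reason),
            class = "allelic_fit")
}

#' @export
print.allelic_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    cat("allelic fit: not estimable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("allelic fit: beta = %.4f (robust se %.4f), z = %.2f, p = %.3g, n = %d\n",
                x$beta_allele, x$se, x$z, x$p, x$fit$n_obs))
  }
  invisible(x)
}

#' Departure of one allele from the scrambled null
#'
#' Same model as [fit_allelic_regression()] with the focal predictor replaced
#' by an indicator of the allele versus its variant-specific scrambled
#' control; the signed coefficient measures transcriptional activity of the
#' allele's element above (positive) or below (negative) the shuffled-core
#' baseline.
#'
#' @param obs observation tibble for one variant (must include scrambled and
#'   the focal allele's rows).
#' @param allele `"risk"` or `"protective"`.
#' @inheritParams fit_allelic_regression
#' @return list with `beta_null`, `se`, `z`, `p`, and the underlying fit.
#' @export
test_vs_scrambled <- function(obs, allele = c("risk", "protective"),
                              hc_type = "HC3") {
  allele <- match.arg(allele)
  obs <- obs[obs$seq_class %in% c("scrambled", allele), , drop = FALSE]
  tab <- table(obs$seq_class)
  if (!all(c(allele, "scrambled") %in% names(tab)) ||
      any(tab[c(allele, "scrambled")] < 2L)) {
    return(list(beta_null = NA_real_, se = NA_real_, z = NA_real_,
                p = NA_real_, fit = NULL,
                reason = "need >= 2 scrambled and >= 2 allele observations"))
  }
  w <- robust_wald(obs, obs$seq_class == allele, hc_type)
  list(beta_null = w$beta, se = w$se, z = w$z, p = w$p, fit = w$fit,
       reason = w$reason)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; `NA` values are passed through
#' and do not count towards the family size.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return vector of adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Per-variant allelic and null-departure statistics for one dataset scope
#'
#' Fits, for every variant, the allelic regression and the two
#' allele-versus-scrambled regressions, then applies BH FDR within the scope:
#' allelic p-values are adjusted across variants, null-departure p-values
#' across all variant-by-allele tests.
#'
#' @param obs observation tibble (any number of variants).
#' @inheritParams fit_allelic_regression
#' @return tibble with one row per variant: effect sizes, robust standard
#'   errors, p-values and FDRs for the allelic and both null-departure tests.
#' @export
analyze_variants <- function(obs, hc_type = "HC3") {
  parts <- split(seq_len(nrow(obs)), obs$variant_id)
  rows <- lapply(names(parts), function(v) {
    o <- obs[parts[[v]], , drop = FALSE]
    fa <- fit_allelic_regression(o, hc_type)
    nr <- test_vs_scrambled(o, "risk", hc_type)
    np <- test_vs_scrambled(o, "protective", hc_type)
    tibble(variant_id = v, n_obs = nrow(o),
           beta_allele = fa$beta_allele, se_allele = fa$se,
           p_allelic = fa$p,
           beta_null_risk = nr$beta_null, p_null_risk = nr$p,
           beta_null_protective = np$beta_null, p_null_protective = np$p)
  })
  res <- bind_rows(rows)
  res$fdr_allelic <- bh_fdr(res$p_allelic)
  fdr_null <- bh_fdr(c(res$p_null_risk, res$p_null_protective))
  res$fdr_null_risk <- fdr_null[seq_len(nrow(res))]
  res$fdr_null_protective <- fdr_null[nrow(res) + seq_len(nrow(res))]
  res
}

#' Drop repeated variants' observations from one library
#'
#' For variants synthesised in more than one library, removes the
#' observations that came from transfections of the specified library, so
#' each variant contributes one library's data to enrichment-style analyses.
#'
#' @param obs observation tibble with a `library_id` column.
#' @param manifest an `mpra_design` object (source of library membership).
#' @param drop_library library whose observations are dropped for repeated
#'   variants.
#' @return the filtered observation tibble.
#' @export
dedupe_repeated_variants <- function(obs, manifest, drop_library = "lib1") {
  stopifnot(inherits(manifest, "mpra_design"))
  libsets <- strsplit(manifest$oligos$library_ids, ";", fixed = TRUE)
  all_libs <- unique(unlist(libsets))
  if (!drop_library %in% all_libs) {
    stop("unknown library id: ", drop_library, call. = FALSE)
  }
  nlib <- vapply(split(libsets, manifest$oligos$variant_id),
                 function(x) length(unique(unlist(x))), integer(1))
  repeated <- names(nlib)[nlib > 1L]
  obs[!(obs$variant_id %in% repeated & obs$library_id == drop_library), ,
      drop = FALSE]
}

#' Classify regulatory function of significant variants
#'
#' Among the alleles whose departure from the scrambled null is significant,
#' all-positive departures make the element an activator, all-negative a
#' repressor, and mixed signs "both"; non-significant variants are "none".
#'
#' @param beta_null_risk,beta_null_protective signed null departures.
#' @param fdr_null_risk,fdr_null_protective their FDRs.
#' @param significant logical significance flag per variant.
#' @param alpha FDR cutoff for a departure to count.
#' @return character vector in `{activator, repressor, both, none}`.
#' @export
classify_regulatory_function <- function(beta_null_risk, fdr_null_risk,
                                         beta_null_protective,
                                         fdr_null_protective,
                                         significant, alpha = 0.01) {
  n <- length(significant)
  out <- rep("none", n)
  for (i in seq_len(n)) {
    if (!isTRUE(significant[i])) next
    betas <- c(beta_null_risk[i], beta_null_protective[i])
    sig <- c(fdr_null_risk[i], fdr_null_protective[i]) < alpha
    sig[is.na(sig)] <- FALSE
    b <- betas[sig]
    out[i] <- if (length(b) == 0L) "none"
      else if (all(b > 0)) "activator"
      else if (all(b < 0)) "repressor"
      else "both"
  }
  out
}

#' Call significant MPRA variants with dual criteria in two scopes
#'
#' A variant is called significant when, in **both** the primary scope (e.g.
#' melanoma-cell transfections only) and the combined scope, its allelic-
#' difference FDR and the FDR of at least one allele's departure from the
#' scrambled null fall below `alpha`. Effect sizes, fold change and the
#' activator/repressor class are reported from the primary scope.
#'
#' @param obs observation tibble covering all transfections.
#' @param primary_transfections transfection ids defining the primary scope.
#' @param combined_transfections transfection ids of the combined scope
#'   (default: all transfections present in `obs`).
#' @param alpha FDR cutoff applied to every criterion.
#' @param hc_type sandwich flavour.
#' @param manifest optional `mpra_design`; required when `dedupe_library`
#'   is set.
#' @param dedupe_library if non-`NULL`, repeated variants' observations from
#'   this library are dropped (see [dedupe_repeated_variants()]) in the
#'   scope(s) named by `dedupe_scope`.
#' @param dedupe_scope `"primary"`, `"both"`, or `"none"`.
#' @return tibble with one row per variant: primary-scope effect and fold
#'   change, p/FDR columns for both scopes, `significant_primary`,
#'   `significant_combined`, `significant`, and `reg_class`.
#' @export
call_mpra_variants <- function(obs, primary_transfections,
                               combined_transfections = NULL,
                               alpha = 0.01, hc_type = "HC3",
                               manifest = NULL, dedupe_library = NULL,
                               dedupe_scope = c("primary", "both", "none")) {
  dedupe_scope <- match.arg(dedupe_scope)
  if (is.null(combined_transfections)) {
    combined_transfections <- unique(obs$transfection_id)
  }
  dd <- function(o) {
    if (is.null(dedupe_library)) return(o)
    if (is.null(manifest)) {
      stop("`manifest` is required for deduplication", call. = FALSE)
    }
    dedupe_repeated_variants(o, manifest, dedupe_library)
  }
  obs_p <- obs[obs$transfection_id %in% primary_transfections, , drop = FALSE]
  obs_c <- obs[obs$transfection_id %in% combined_transfections, , drop = FALSE]
  if (dedupe_scope %in% c("primary", "both")) obs_p <- dd(obs_p)
  if (dedupe_scope == "both") obs_c <- dd(obs_c)
  res_p <- analyze_variants(obs_p, hc_type)
  res_c <- analyze_variants(obs_c, hc_type)
  names(res_c) <- ifelse(names(res_c) == "variant_id", "variant_id",
                         paste0(names(res_c), "_combined"))
  calls <- left_join(res_p, res_c, by = "variant_id")
  sig_scope <- function(fa, fr, fp) {
    !is.na(fa) & fa < alpha &
      pmin(ifelse(is.na(fr), Inf, fr), ifelse(is.na(fp), Inf, fp)) < alpha
  }
  calls$significant_primary <- sig_scope(calls$fdr_allelic,
                                         calls$fdr_null_risk,
                                         calls$fdr_null_protective)
  calls$significant_combined <- sig_scope(calls$fdr_allelic_combined,
                                          calls$fdr_null_risk_combined,
                                          calls$fdr_null_protective_combined)
  calls$significant <- calls$significant_primary & calls$significant_combined
  calls$fold_change <- 2^abs(calls$beta_allele)
  calls$direction <- ifelse(is.na(calls$beta_allele), NA_character_,
                            ifelse(calls$beta_allele >= 0, "risk_higher",
                                   "protective_higher"))
  calls$reg_class <- classify_regulatory_function(
    calls$beta_null_risk, calls$fdr_null_risk,
    calls$beta_null_protective, calls$fdr_null_protective,
    calls$significant, alpha)
  calls
}

#' Volcano-plot-ready table
#'
#' Effect size and -log10 allelic p-value per variant, with significance and
#' regulatory-class annotation, ready for plotting.
#'
#' @param calls output of [call_mpra_variants()].
#' @return tibble with `variant_id`, `beta_allele`, `neg_log10_p`,
#'   `significant`, `reg_class`.
#' @export
volcano_table <- function(calls) {
  tibble(variant_id = calls$variant_id,
         beta_allele = calls$beta_allele,
         neg_log10_p = -log10(calls$p_allelic),
         significant = calls$significant,
         reg_class = calls$reg_class)
}
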