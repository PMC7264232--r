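# OLS + sandwich Wald machinery, BH FDR, dual-criteria calling.

random_design <- function(n, n_trans = 3) {
  tibble::tibble(
    barcode = sprintf("b%04d", seq_len(n)),
    variant_id = "v1",
    seq_class = sample(c("risk", "protective"), n, replace = TRUE,
                       prob = c(.5, .5)),
    orientation = sample(c("forward", "reverse"), n, replace = TRUE),
    transfection_id = sample(sprintf("T%02d", seq_len(n_trans)), n, replace = TRUE),
    cell_line = "UACC903", promoter = "TATA", library_id = "lib1",
    log2_ratio = rnorm(n)
  )
}

test_that("balanced single-covariate data reduce the allele effect to a mean difference", {
  obs <- toy_obs(means = c(risk = 1.3, protective = 0.4, scrambled = 0),
                 transfections = "T01", orientations = "forward",
                 noise_sd = 0.2)
  f <- fit_allelic_regression(obs)
  md <- mean(obs$log2_ratio[obs$seq_class == "risk"]) -
    mean(obs$log2_ratio[obs$seq_class == "protective"])
  expect_equal(f$beta_allele, md, tolerance = 1e-10)
  # balanced scrambled comparison equals the two-sample mean difference too
  ts <- test_vs_scrambled(obs, "risk")
  md2 <- mean(obs$log2_ratio[obs$seq_class == "risk"]) -
    mean(obs$log2_ratio[obs$seq_class == "scrambled"])
  expect_equal(ts$beta_null, md2, tolerance = 1e-10)
})

test_that("coefficients and sandwich covariances match a normal-equations oracle", {
  withr::with_seed(42, {
    for (i in 1:30) {
      n <- sample(30:120, 1)
      obs <- random_design(n, n_trans = sample(2:5, 1))
      # guard: ensure both alleles present
      obs$seq_class[1:4] <- c("risk", "risk", "protective", "protective")
      for (hc in c("HC0", "HC1", "HC2", "HC3")) {
        f <- fit_allelic_regression(obs, hc_type = hc)
        X <- f$fit$coefficients
        # rebuild the same design for the oracle
        lev <- sort(unique(obs$transfection_id))
        Xo <- cbind(1, as.numeric(obs$seq_class == "risk"),
                    as.numeric(obs$orientation == "reverse"))
        for (l in lev[-1]) Xo <- cbind(Xo, as.numeric(obs$transfection_id == l))
        o <- oracle_ols_hc(Xo, obs$log2_ratio, hc)
        expect_equal(unname(f$fit$coefficients), o$beta, tolerance = 1e-8)
        expect_equal(unname(f$fit$robust_cov), unname(o$V), tolerance = 1e-8)
        expect_equal(unname(f$fit$ols_cov), unname(o$ols_cov), tolerance = 1e-8)
        expect_equal(unname(f$fit$leverages), o$leverages, tolerance = 1e-8)
      }
    }
  })
})

test_that("fits agree with the reference sandwich/lmtest implementation", {
  withr::with_seed(7, {
    obs <- random_design(80, n_trans = 4)
    obs$seq_class[1:4] <- c("risk", "risk", "protective", "protective")
    f <- fit_allelic_regression(obs, hc_type = "HC3")
    m <- stats::lm(log2_ratio ~ I(seq_class == "risk") +
                     I(orientation == "reverse") + transfection_id, data = obs)
    v <- sandwich::vcovHC(m, type = "HC3")
    expect_equal(f$beta_allele, unname(coef(m)[2]), tolerance = 1e-10)
    expect_equal(f$se, sqrt(v[2, 2]), tolerance = 1e-10)
    ct <- lmtest::coeftest(m, vcov. = v)
    # our Wald p uses the standard normal reference
    expect_equal(f$p, 2 * pnorm(-abs(ct[2, "t value"])), tolerance = 1e-10)
  })
})

test_that("regression internals satisfy the OLS identities", {
  withr::with_seed(8, {
    obs <- random_design(100, n_trans = 4)
    obs$seq_class[1:4] <- c("risk", "risk", "protective", "protective")
    f <- fit_allelic_regression(obs)$fit
    # X'e = 0 and the hat-trace equals the rank
    lev <- sort(unique(obs$transfection_id))
    X <- cbind(1, as.numeric(obs$seq_class == "risk"),
               as.numeric(obs$orientation == "reverse"))
    for (l in lev[-1]) X <- cbind(X, as.numeric(obs$transfection_id == l))
    expect_lt(max(abs(crossprod(X, f$residuals))), 1e-8)
    expect_equal(sum(f$leverages), f$rank, tolerance = 1e-8)
    ev <- eigen(f$robust_cov, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-12))
  })
})

test_that("robust and OLS standard errors converge under homoskedastic noise", {
  withr::with_seed(9, {
    obs <- random_design(5000, n_trans = 5)
    f <- fit_allelic_regression(obs)$fit
    ratio <- sqrt(f$robust_cov["predictor", "predictor"] /
                    f$ols_cov["predictor", "predictor"])
    expect_lt(abs(ratio - 1), 0.05)
  })
})

test_that("degenerate designs degrade deterministically", {
  # all observations one allele -> not estimable
  obs <- toy_obs()
  f <- fit_allelic_regression(obs[obs$seq_class == "risk", ])
  expect_true(is.na(f$beta_allele))
  # allele confounded with transfection -> collinear dummy dropped, effect kept
  obs2 <- toy_obs(transfections = c("T01", "T02"))
  obs2 <- obs2[(obs2$seq_class == "risk") == (obs2$transfection_id == "T02") |
                 obs2$seq_class == "scrambled", ]
  f2 <- fit_allelic_regression(obs2)
  expect_true(is.na(f2$beta_allele) || length(f2$dropped_columns) > 0)
  # too few scrambled observations
  obs3 <- toy_obs()
  ts <- test_vs_scrambled(obs3[obs3$seq_class != "scrambled", ], "risk")
  expect_true(is.na(ts$p))
})

test_that("a shifted allele separates sharply from its scrambled control", {
  withr::with_seed(10, {
    obs <- toy_obs(means = c(risk = 1, protective = 0, scrambled = 0),
                   noise_sd = 0.05)
    ts <- test_vs_scrambled(obs, "risk")
    expect_gt(ts$beta_null, 0.8)
    expect_lt(ts$p, 1e-10)
    tp <- test_vs_scrambled(obs, "protective")
    expect_gt(tp$p, 1e-4)
  })
})

test_that("BH adjustment matches the step-up definition and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.73), 0.73)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  p_na <- c(0.01, NA, 0.04)
  out <- bh_fdr(p_na)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_fdr(c(0.01, 0.04)))
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- runif(sample(3:40, 1))
      expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
      perm <- sample(length(p))
      expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]), tolerance = 1e-12)
    }
  })
})

test_that("per-scope FDR families are variants (allelic) and variant-by-allele (null)", {
  withr::with_seed(12, {
    obs <- dplyr::bind_rows(lapply(1:6, function(i) {
      toy_obs(means = c(risk = 0.1 * i, protective = 0, scrambled = 0),
              noise_sd = 0.3, variant_id = paste0("v", i))
    }))
    res <- analyze_variants(obs)
    expect_identical(nrow(res), 6L)
    expect_equal(res$fdr_allelic, bh_fdr(res$p_allelic))
    joint <- bh_fdr(c(res$p_null_risk, res$p_null_protective))
    expect_equal(res$fdr_null_risk, joint[1:6])
    expect_equal(res$fdr_null_protective, joint[7:12])
    expect_true(all(res$fdr_allelic >= res$p_allelic, na.rm = TRUE))
  })
})

test_that("dual-criteria calling requires every criterion in both scopes", {
  withr::with_seed(13, {
    # v_sig: strong allelic difference + activity in all transfections
    # v_scope: allelic difference only in the primary transfections
    # v_null: nothing
    prim <- c("T01", "T02"); comb <- c("T01", "T02", "T03", "T04")
    mk <- function(id, means_prim, means_comb) {
      dplyr::bind_rows(
        toy_obs(means_prim, transfections = prim, variant_id = id, noise_sd = 0.1),
        toy_obs(means_comb, transfections = c("T03", "T04"), variant_id = id,
                noise_sd = 0.1)
      )
    }
    obs <- dplyr::bind_rows(
      mk("v_sig", c(risk = 1.6, protective = 0.8, scrambled = 0),
         c(risk = 1.6, protective = 0.8, scrambled = 0)),
      mk("v_scope", c(risk = 1.6, protective = 0.8, scrambled = 0),
         c(risk = 0.8, protective = 1.6, scrambled = 0)),
      mk("v_null", c(risk = 1, protective = 1, scrambled = 1),
         c(risk = 1, protective = 1, scrambled = 1))
    )
    calls <- call_mpra_variants(obs, prim, comb)
    got <- setNames(calls$significant, calls$variant_id)
    expect_true(got["v_sig"])
    # the reversed combined-scope effect cancels the combined allelic test
    expect_false(got["v_scope"])
    expect_false(got["v_null"])
    expect_true(calls$significant_primary[calls$variant_id == "v_scope"])
    expect_true(all(calls$fold_change >= 1, na.rm = TRUE))
    expect_true(all((calls$significant_primary & calls$significant_combined) ==
                      calls$significant))
    vt <- volcano_table(calls)
    expect_identical(nrow(vt), 3L)
    expect_equal(vt$neg_log10_p, -log10(calls$p_allelic))
  })
})

test_that("regulatory classes follow the sign pattern of significant departures", {
  cls <- classify_regulatory_function(
    beta_null_risk = c(1, -1, 1, -0.5, 1),
    fdr_null_risk = c(0.001, 0.001, 0.001, 0.001, 0.5),
    beta_null_protective = c(0.5, -0.5, -1, 0.2, 0.5),
    fdr_null_protective = c(0.001, 0.001, 0.001, 0.5, 0.001),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE), alpha = 0.01)
  expect_identical(cls, c("activator", "repressor", "both", "repressor",
                          "activator"))
  expect_identical(
    classify_regulatory_function(1, 0.001, 1, 0.001, FALSE), "none")
})

test_that("repeated variants drop exactly the configured library's observations", {
  v <- dplyr::bind_rows(
    toy_variant("shared", libraries = "lib1;lib2"),
    toy_variant("only1", libraries = "lib1")
  )
  man <- build_library(v, seed = 3)
  obs <- dplyr::bind_rows(
    toy_obs(variant_id = "shared", library_id = "lib1", transfections = "T01"),
    toy_obs(variant_id = "shared", library_id = "lib2", transfections = "T02"),
    toy_obs(variant_id = "only1", library_id = "lib1", transfections = "T01")
  )
  out <- dedupe_repeated_variants(obs, man, "lib1")
  expect_identical(sum(out$variant_id == "shared" & out$library_id == "lib1"), 0L)
  expect_identical(sum(out$variant_id == "shared" & out$library_id == "lib2"),
                   sum(obs$variant_id == "shared" & obs$library_id == "lib2"))
  expect_identical(sum(out$variant_id == "only1"),
                   sum(obs$variant_id == "only1"))
  expect_identical(nrow(out), nrow(obs) -
                     sum(obs$variant_id == "shared" & obs$library_id == "lib1"))
  expect_error(dedupe_repeated_variants(obs, man, "lib9"), "unknown library")
})
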