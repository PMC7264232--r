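# Generative MPRA model with known ground truth: variants, design, DNA/RNA
# counts, FASTQ reads, and companion eQTL/ASE/mass-spec tables.

#' Simulation parameters
#'
#' Defaults describe a study-scale experiment: ~5% of variants carry a true
#' allelic effect with fold changes uniform on 1.13-3.49, elements are
#' activators/neutral/repressors at one log2 unit around the scrambled
#' baseline, a mild strand effect and per-transfection offsets, per-tag
#' Gaussian noise drawn independently for every tag-by-transfection cell (the
#' regression's replication unit), DNA tag abundances from a symmetric
#' Dirichlet, Dirichlet-multinomial RNA counts, and sequencing depth of
#' 5e4 reads per tag scaled by a single factor for desk-scale runs.
#'
#' @param n_variants number of variants to simulate.
#' @param frac_true_effects fraction of variants with a non-zero allelic
#'   effect.
#' @param fold_range linear-scale range of true allelic fold changes.
#' @param mu_active log2 activity of an active element above scrambled.
#' @param mu_scrambled baseline log2 activity of scrambled sequences.
#' @param activity_probs probabilities that an element is an activator,
#'   neutral, or a repressor (named, summing to 1).
#' @param strand_effect additive log2 offset of reverse-orientation segments.
#' @param transfection_sd standard deviation of per-transfection offsets.
#' @param tag_noise_sd per-tag-per-transfection Gaussian noise sd (log2).
#' @param depth_per_tag_dna,depth_per_tag_rna expected reads per tag before
#'   scaling.
#' @param scale single desk-scale factor applied to both depths.
#' @param dirichlet_concentration symmetric Dirichlet parameter for DNA tag
#'   abundances (larger = more even).
#' @param overdispersion mean per-tag Dirichlet shape of the RNA
#'   Dirichlet-multinomial (`Inf` disables overdispersion).
#' @param read_length,error_rate FASTQ emission: read length (>= 30) and
#'   per-base substitution rate.
#' @param reps_per_condition transfection replicates per (library, cell line,
#'   promoter) condition.
#' @param extra_primary_rep add one extra melanoma-line replicate per library
#'   (9 transfection levels per library; 18 for a two-library design).
#' @param indel_frac fraction of simulated variants that are indels.
#' @param flank_length flank length of simulated variants.
#' @param n_het,ase_true_ratio,ct_sd,base_ct companion ASE table: number of
#'   heterozygotes, true cDNA/gDNA allelic ratio, Ct noise sd, baseline Ct.
#' @param n_proteins,n_planted,plant_iqr,ms_sd companion mass-spec table:
#'   background size, number of planted allelic binders, how many IQRs
#'   beyond the quartile they are planted, background log-ratio sd.
#' @param eqtl_concordance fraction of eQTL records whose harmonised slope
#'   direction matches the true MPRA effect.
#' @param eqtl_slope_mean,eqtl_slope_sd magnitude distribution of eQTL
#'   slopes.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_variants = 100L, frac_true_effects = 0.05,
                       fold_range = c(1.13, 3.49), mu_active = 1,
                       mu_scrambled = 0,
                       activity_probs = c(activator = 0.5, none = 0.3,
                                          repressor = 0.2),
                       strand_effect = 0.2, transfection_sd = 0.3,
                       tag_noise_sd = 0.3,
                       depth_per_tag_dna = 5e4, depth_per_tag_rna = 5e4,
                       scale = 1, dirichlet_concentration = 50,
                       overdispersion = 100, read_length = 50L,
                       error_rate = 0, reps_per_condition = 2L,
                       extra_primary_rep = TRUE, indel_frac = 0,
                       flank_length = 100L, n_het = 27L,
                       ase_true_ratio = 1.5, ct_sd = 0.15, base_ct = 28,
                       n_proteins = 500L, n_planted = 5L, plant_iqr = 3,
                       ms_sd = 0.3, eqtl_concordance = 1,
                       eqtl_slope_mean = 0.7, eqtl_slope_sd = 0.15) {
  if (fold_range[1] < 1) stop("fold_range low must be >= 1", call. = FALSE)
  if (read_length < 30L) stop("read_length must be >= 30", call. = FALSE)
  p <- as.list(environment())
  structure(p, class = "sim_params")
}

#' Simulate variant specifications
#'
#' Biallelic SNVs (optionally indels) with random flanking sequence long
#' enough for the test window, LD and annotation-provenance fields populated.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return tibble of variant specifications suitable for [build_library()].
#' @export
simulate_variants <- function(params = sim_params(), seed = 1L) {
  n <- params$n_variants
  withr::with_seed(as.integer(seed), {
    is_indel <- runif(n) < params$indel_frac
    ref <- character(n); alt <- character(n)
    for (i in seq_len(n)) {
      if (is_indel[i]) {
        short <- random_dna(1L, 1L)
        ins_len <- sample(2:3, 1L)
        long <- paste0(short, random_dna(1L, ins_len))
        if (runif(1) < 0.5) { ref[i] <- short; alt[i] <- long }
        else { ref[i] <- long; alt[i] <- short }
      } else {
        pair <- sample(DNA_BASES, 2L)
        ref[i] <- pair[1]; alt[i] <- pair[2]
      }
    }
    risk_is_ref <- runif(n) < 0.5
    tb <- tibble(
      variant_id = sprintf("var%04d", seq_len(n)),
      chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
      pos = sample.int(1e6L, n, replace = TRUE),
      risk_allele = ifelse(risk_is_ref, ref, alt),
      protective_allele = ifelse(risk_is_ref, alt, ref),
      reference_allele = ref,
      left_flank = random_dna(n, params$flank_length),
      right_flank = random_dna(n, params$flank_length),
      lead_snp_id = sprintf("lead%02d", 1L + (seq_len(n) - 1L) %% 16L),
      ld_r2_with_lead = round(runif(n, 0.4, 1), 3),
      locus_label = sprintf("locus%02d", 1L + (seq_len(n) - 1L) %% 16L),
      is_negative_control = FALSE,
      is_indel = is_indel
    )
    tb
  })
}

#' Simulate annotation tracks around variant positions
#'
#' A configurable fraction of variants receive a covering peak in each
#' track; decoy peaks elsewhere exercise the overlap machinery.
#'
#' @param variants tibble from [simulate_variants()].
#' @param track_names names of the tracks to emit.
#' @param frac_in_peak per-track probability that a variant is covered.
#' @param seed integer seed.
#' @return named list of BED-convention (0-based half-open) data frames.
#' @export
simulate_tracks <- function(variants, track_names = c("DHS", "H3K27Ac"),
                            frac_in_peak = 0.5, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    out <- lapply(seq_along(track_names), function(k) {
      covered <- runif(nrow(variants)) < frac_in_peak
      pos0 <- variants$pos - 1L
      peaks <- data.frame(
        chrom = variants$chrom[covered],
        start = pos0[covered] - sample.int(200L, sum(covered), replace = TRUE),
        end = pos0[covered] + sample.int(200L, sum(covered), replace = TRUE)
      )
      st <- sample.int(2e6L, 50L) + 1e6L
      decoys <- data.frame(
        chrom = sample(unique(variants$chrom), 50L, replace = TRUE),
        start = st,
        end = st + sample.int(500L, 50L)
      )
      rbind(peaks, decoys)
    })
    names(out) <- track_names
    out
  })
}

#' Default transfection layout for a design
#'
#' One DNA-input sample per library plus RNA samples for each transfection:
#' per library, melanoma (UACC903) and HEK293FT cell lines, each with and
#' without a minimal TATA promoter, `reps_per_condition` replicates each,
#' plus (optionally) one extra melanoma replicate — 9 transfection levels per
#' library, 18 for a two-library design.
#'
#' @param manifest an `mpra_design` object.
#' @param params a [sim_params()] object.
#' @return sample-sheet tibble with DNA and RNA rows.
#' @export
simulate_sample_sheet <- function(manifest, params = sim_params()) {
  libs <- sort(unique(unlist(strsplit(manifest$oligos$library_ids, ";",
                                      fixed = TRUE))))
  rows <- list()
  tcount <- 0L
  for (l in libs) {
    rows[[length(rows) + 1L]] <- tibble(
      sample_id = paste0("DNA_", l), material = "DNA",
      transfection_id = NA_character_, cell_line = NA_character_,
      promoter = NA_character_, library_id = l, dna_sample_id = NA_character_)
    grid <- expand.grid(cell_line = c("UACC903", "HEK293FT"),
                        promoter = c("TATA", "none"),
                        rep = seq_len(params$reps_per_condition),
                        stringsAsFactors = FALSE)
    if (params$extra_primary_rep) {
      grid <- rbind(grid, data.frame(cell_line = "UACC903", promoter = "TATA",
                                     rep = params$reps_per_condition + 1L))
    }
    for (i in seq_len(nrow(grid))) {
      tcount <- tcount + 1L
      tid <- sprintf("T%02d", tcount)
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = paste0("RNA_", tid), material = "RNA",
        transfection_id = tid, cell_line = grid$cell_line[i],
        promoter = grid$promoter[i], library_id = l,
        dna_sample_id = paste0("DNA_", l))
    }
  }
  bind_rows(rows)
}

# Per-variant ground truth: allelic effect and latent element activities.
draw_truth <- function(variant_ids, params) {
  n <- length(variant_ids)
  has_effect <- seq_len(n) <= round(params$frac_true_effects * n)
  has_effect <- sample(has_effect)
  beta <- numeric(n)
  lo <- log2(params$fold_range[1]); hi <- log2(params$fold_range[2])
  beta[has_effect] <- runif(sum(has_effect), lo, hi) *
    sample(c(-1, 1), sum(has_effect), replace = TRUE)
  base <- sample(names(params$activity_probs), n, replace = TRUE,
                 prob = params$activity_probs)
  mu_base <- c(activator = params$mu_active, none = 0,
               repressor = -params$mu_active)[base]
  a_prot <- params$mu_scrambled + mu_base
  a_risk <- a_prot + beta
  true_class <- vapply(seq_len(n), function(i) {
    s <- c(a_risk[i], a_prot[i]) - params$mu_scrambled
    s <- sign(s[s != 0])
    if (length(s) == 0L) "none"
    else if (all(s > 0)) "activator"
    else if (all(s < 0)) "repressor"
    else "both"
  }, character(1))
  tibble(variant_id = variant_ids, beta_allele = beta,
         activity_risk = unname(a_risk), activity_protective = unname(a_prot),
         true_class = true_class)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate DNA and RNA tag counts for a design
#'
#' DNA tag proportions are Dirichlet-distributed and sequenced
#' multinomially. Per transfection, each tag's latent log2 activity is the
#' sum of its sequence-class activity, the allelic effect (risk tags), the
#' strand effect (reverse tags), the transfection offset, and independent
#' per-tag-per-transfection Gaussian noise; RNA proportions are proportional
#' to DNA abundance times 2^activity and sequenced with
#' Dirichlet-multinomial overdispersion.
#'
#' @param manifest an `mpra_design` object.
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @param sample_sheet optional sample sheet (default
#'   [simulate_sample_sheet()]).
#' @param truth optional explicit truth tibble (`variant_id`, `beta_allele`,
#'   `activity_risk`, `activity_protective`, `true_class`), e.g. for
#'   recovery studies at fixed fold changes; drawn from `params` when `NULL`.
#' @return list with `counts` (barcode x sample matrix), `sample_sheet`,
#'   `truth` (per-variant tibble), `transfection_offsets`, and
#'   `dna_proportions` (the latent Dirichlet tag abundances, per library).
#' @export
simulate_counts <- function(manifest, params = sim_params(), seed = 1L,
                            sample_sheet = NULL, truth = NULL) {
  stopifnot(inherits(manifest, "mpra_design"))
  if (is.null(sample_sheet)) sample_sheet <- simulate_sample_sheet(manifest, params)
  ol <- manifest$oligos
  withr::with_seed(as.integer(seed), {
    if (is.null(truth)) truth <- draw_truth(unique(ol$variant_id), params)
    rna <- sample_sheet[sample_sheet$material == "RNA", ]
    gamma <- setNames(rnorm(nrow(rna), 0, params$transfection_sd),
                      rna$transfection_id)
    counts <- matrix(0L, nrow(ol), nrow(sample_sheet),
                     dimnames = list(ol$barcode, sample_sheet$sample_id))
    m <- match(ol$variant_id, truth$variant_id)
    class_act <- ifelse(ol$seq_class == "scrambled", params$mu_scrambled,
                        ifelse(ol$seq_class == "risk",
                               truth$activity_risk[m],
                               truth$activity_protective[m]))
    strand_add <- params$strand_effect * (ol$orientation == "reverse")
    libs_of <- strsplit(ol$library_ids, ";", fixed = TRUE)
    dna_props <- list()
    for (l in unique(sample_sheet$library_id)) {
      in_lib <- vapply(libs_of, function(x) l %in% x, logical(1))
      nt <- sum(in_lib)
      p <- rdirichlet1(rep(params$dirichlet_concentration, nt))
      dna_props[[l]] <- setNames(p, ol$barcode[in_lib])
      depth_dna <- round(params$depth_per_tag_dna * params$scale * nt)
      counts[in_lib, paste0("DNA_", l)] <-
        rmultinom(1L, depth_dna, p)[, 1L]
      rna_l <- rna[rna$library_id == l, ]
      depth_rna <- round(params$depth_per_tag_rna * params$scale * nt)
      for (j in seq_len(nrow(rna_l))) {
        act <- class_act[in_lib] + strand_add[in_lib] +
          gamma[rna_l$transfection_id[j]] +
          rnorm(nt, 0, params$tag_noise_sd)
        w <- p * 2^act
        w <- w / sum(w)
        q <- if (is.finite(params$overdispersion)) {
          rdirichlet1(params$overdispersion * nt * w)
        } else w
        counts[in_lib, rna_l$sample_id[j]] <- rmultinom(1L, depth_rna, q)[, 1L]
      }
    }
    list(counts = counts, sample_sheet = sample_sheet, truth = truth,
         transfection_offsets = gamma, dna_proportions = dna_props)
  })
}

#' Emit FASTQ reads for one sample's tag counts
#'
#' Each tag yields `count` reads of the form
#' `barcode + read context + random filler`, with constant quality, optional
#' uniform per-base substitution errors, and deterministic seeded shuffling
#' of read order. Files ending in `.gz` are gzip-compressed.
#'
#' @param counts named count vector (names are barcodes).
#' @param path output FASTQ path.
#' @param params a [sim_params()] object (`read_length`, `error_rate`).
#' @param seed integer seed.
#' @return invisibly, the number of reads written.
#' @export
emit_fastq <- function(counts, path, params = sim_params(), seed = 1L) {
  if (params$read_length < 30L) stop("read_length must be >= 30", call. = FALSE)
  counts <- counts[counts > 0]
  n <- sum(counts)
  withr::with_seed(as.integer(seed), {
    prefix <- paste0(rep(names(counts), counts), MPRA_READ_CONTEXT)
    fill_len <- params$read_length - nchar(prefix[1])
    reads <- if (fill_len > 0L) paste0(prefix, random_dna(n, fill_len)) else prefix
    reads <- reads[sample.int(n)]
    if (params$error_rate > 0) {
      L <- params$read_length
      rm_ <- matrix(unlist(strsplit(reads, "", fixed = TRUE)), nrow = n,
                    byrow = TRUE)
      hit <- which(matrix(runif(n * L) < params$error_rate, n, L))
      if (length(hit) > 0L) {
        # substitute with one of the three other bases
        old <- rm_[hit]
        shift <- sample.int(3L, length(hit), replace = TRUE)
        rm_[hit] <- DNA_BASES[(match(old, DNA_BASES) - 1L + shift) %% 4L + 1L]
      }
      reads <- do.call(paste0, as.data.frame(rm_, stringsAsFactors = FALSE))
    }
    qual <- strrep("I", params$read_length)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@read", seq_len(n), "\n", reads, "\n+\n", qual), con)
  })
  invisible(n)
}

#' Simulate companion eQTL, ASE, and mass-spec evidence tables
#'
#' eQTL records are generated per variant with a configurable fraction of
#' direction-concordant slopes (harmonised to the true MPRA effect); the ASE
#' table holds Ct triplicates for heterozygous samples at a chosen true
#' allelic ratio; the mass-spec table holds label-swapped log ratios with
#' planted allelic binders.
#'
#' @param variants tibble from [simulate_variants()].
#' @param truth truth tibble from [simulate_counts()].
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return list with `eqtl`, `ase`, `ms` tibbles; planted MS outliers are
#'   marked in the `planted` column.
#' @export
simulate_companion_tables <- function(variants, truth, params = sim_params(),
                                      seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n <- nrow(truth)
    m <- match(truth$variant_id, variants$variant_id)
    eff_is_risk <- runif(n) < 0.5
    concordant <- runif(n) < params$eqtl_concordance
    truth_sign <- ifelse(truth$beta_allele == 0,
                         sample(c(-1, 1), n, replace = TRUE),
                         sign(truth$beta_allele))
    slope_risk <- abs(rnorm(n, params$eqtl_slope_mean, params$eqtl_slope_sd)) *
      ifelse(concordant, truth_sign, -truth_sign)
    eqtl <- tibble(
      variant_id = truth$variant_id,
      gene_id = sprintf("GENE%04d", seq_len(n)),
      effect_allele = ifelse(eff_is_risk, variants$risk_allele[m],
                             variants$protective_allele[m]),
      slope = ifelse(eff_is_risk, slope_risk, -slope_risk),
      nominal_p = 10^runif(n, -15, -6),
      significance_threshold = 1e-5,
      significant = TRUE,
      concordant_truth = concordant
    )

    dct_cdna <- -log2(params$ase_true_ratio)
    ase <- tibble(sample_id = sprintf("het%02d", seq_len(params$n_het)),
                  heterozygous = TRUE)
    for (rep_i in 1:3) {
      ase[[paste0("ct_a_cdna_", rep_i)]] <-
        rnorm(params$n_het, params$base_ct + dct_cdna / 2, params$ct_sd)
      ase[[paste0("ct_c_cdna_", rep_i)]] <-
        rnorm(params$n_het, params$base_ct - dct_cdna / 2, params$ct_sd)
      ase[[paste0("ct_a_gdna_", rep_i)]] <-
        rnorm(params$n_het, params$base_ct, params$ct_sd)
      ase[[paste0("ct_c_gdna_", rep_i)]] <-
        rnorm(params$n_het, params$base_ct, params$ct_sd)
    }

    np <- params$n_proteins
    x <- rnorm(np, 0, params$ms_sd)
    y <- rnorm(np, 0, params$ms_sd)
    planted <- rep("none", np)
    if (params$n_planted > 0L) {
      idx <- sample.int(np, params$n_planted)
      dir_a <- runif(params$n_planted) < 0.5
      qx <- quantile(x, c(0.25, 0.75), names = FALSE)
      qy <- quantile(y, c(0.25, 0.75), names = FALSE)
      iqx <- qx[2] - qx[1]; iqy <- qy[2] - qy[1]
      x[idx] <- ifelse(dir_a, qx[2] + params$plant_iqr * iqx,
                       qx[1] - params$plant_iqr * iqx)
      y[idx] <- ifelse(dir_a, qy[1] - params$plant_iqr * iqy,
                       qy[2] + params$plant_iqr * iqy)
      planted[idx] <- ifelse(dir_a, "A_preferential", "C_preferential")
    }
    ms <- tibble(protein_id = sprintf("P%05d", seq_len(np)),
                 log_ratio_rep1 = x, log_ratio_rep2 = y, planted = planted)
    list(eqtl = eqtl, ase = ase, ms = ms)
  })
}

#' Simulate a complete MPRA experiment
#'
#' Convenience wrapper: variants, design manifest, sample sheet, counts with
#' truth, and filtered activity observations, all from one seed.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @param design a [design_params()] object.
#' @return list with `variants`, `manifest`, `counts`, `sample_sheet`,
#'   `truth`, `transfection_offsets`, `observations`.
#' @export
simulate_mpra <- function(params = sim_params(), seed = 1L,
                          design = design_params()) {
  variants <- simulate_variants(params, seed = derive_seed(seed, 1L))
  manifest <- build_library(variants, design,
                            seed = derive_seed(seed, 2L))
  sim <- simulate_counts(manifest, params, seed = derive_seed(seed, 3L))
  obs <- mpra_observations(sim$counts, sim$sample_sheet, manifest)
  list(variants = variants, manifest = manifest, counts = sim$counts,
       sample_sheet = sim$sample_sheet, truth = sim$truth,
       transfection_offsets = sim$transfection_offsets, observations = obs)
}
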