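# Small fixtures built in code.

rand_flank <- function(len = 100) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

toy_variant <- function(id = "v1", risk = "A", protective = "C",
                        reference = risk, left = NULL, right = NULL,
                        libraries = "lib1", r2 = 0.9, neg = FALSE) {
  tibble::tibble(
    variant_id = id, chrom = "chr1", pos = 5000L,
    risk_allele = risk, protective_allele = protective,
    reference_allele = reference,
    left_flank = if (is.null(left)) rand_flank() else left,
    right_flank = if (is.null(right)) rand_flank() else right,
    lead_snp_id = "lead1", ld_r2_with_lead = r2, locus_label = "locusA",
    is_negative_control = neg, library_ids = libraries
  )
}

# Balanced observation tibble for one variant, built directly from group
# means plus noise; `classes` names map to mean log2 ratios.
toy_obs <- function(means = c(risk = 1, protective = 0, scrambled = 0),
                    n_per = 10, transfections = c("T01", "T02"),
                    orientations = c("forward", "reverse"), noise_sd = 0,
                    variant_id = "v1", library_id = "lib1") {
  g <- expand.grid(seq_class = names(means), orientation = orientations,
                   transfection_id = transfections, rep = seq_len(n_per),
                   stringsAsFactors = FALSE)
  tibble::tibble(
    barcode = sprintf("BC%04d", seq_len(nrow(g))),
    variant_id = variant_id,
    seq_class = g$seq_class,
    orientation = g$orientation,
    transfection_id = g$transfection_id,
    cell_line = "UACC903", promoter = "TATA", library_id = library_id,
    log2_ratio = means[g$seq_class] + rnorm(nrow(g), 0, noise_sd)
  )
}
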