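# Oligo library construction: variant selection, scrambled cores, barcode
# generation, and assembly of the full design manifest.

#' Select candidate variants by LD and annotation overlap
#'
#' Keeps variants in sufficient LD with their lead SNP whose genomic position
#' falls inside annotation intervals satisfying a boolean rule over track
#' names, e.g. `"DHS | (H3K27Ac & H3K4Me1) | (H3K27Ac & H3K4Me3) | FAIRE"`.
#' Negative-control variants (high-LD variants deliberately outside all
#' functional annotation) are excluded unless explicitly whitelisted.
#'
#' @param variants tibble with at least `variant_id`, `chrom`, `pos` (1-based),
#'   `ld_r2_with_lead`, and optionally `is_negative_control`.
#' @param tracks named list of annotation tracks, each a data frame with
#'   `chrom`, `start`, `end` in 0-based half-open (BED) convention.
#' @param rule character scalar; a boolean expression over `names(tracks)`.
#' @param r2_threshold minimum LD r-squared with the lead SNP.
#' @param keep_negative_controls if `TRUE`, rows flagged
#'   `is_negative_control` are passed through regardless of the rule.
#' @return the selected rows of `variants`.
#' @export
select_candidate_variants <- function(variants, tracks, rule,
                                      r2_threshold = 0.4,
                                      keep_negative_controls = FALSE) {
  if (length(tracks) == 0L) stop("`tracks` must be non-empty", call. = FALSE)
  expr <- parse(text = rule)[[1]]
  used <- all.vars(expr)
  unknown <- setdiff(used, names(tracks))
  if (length(unknown) > 0L) {
    stop("rule references unknown track(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  track_chroms <- unique(unlist(lapply(tracks, function(t) unique(t$chrom))))
  off <- !(variants$chrom %in% track_chroms)
  if (any(off)) {
    warning(sprintf("%d variant(s) on chromosomes absent from all tracks; %s",
                    sum(off), "treated as overlapping no peak"))
  }
  qry <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  hits <- lapply(tracks[used], function(t) {
    # BED [start, end) -> 1-based closed [start+1, end]
    gr <- GenomicRanges::GRanges(t$chrom, IRanges::IRanges(t$start + 1L, t$end))
    # disjoint seqlevels between query and track are expected (own warning above)
    suppressWarnings(GenomicRanges::countOverlaps(qry, gr) > 0L)
  })
  pass_rule <- eval(expr, envir = hits)
  neg <- if ("is_negative_control" %in% names(variants)) {
    isTRUE_v(variants$is_negative_control)
  } else rep(FALSE, nrow(variants))
  keep <- variants$ld_r2_with_lead >= r2_threshold & pass_rule & !neg
  if (keep_negative_controls) keep <- keep | neg
  variants[keep, , drop = FALSE]
}

isTRUE_v <- function(x) !is.na(x) & x

#' Scramble the core sequence around a variant
#'
#' Returns a uniform-random permutation of `core`, rejection-sampled until the
#' permuted core creates no homopolymer run longer than
#' `params$max_homopolymer` and no KpnI/XbaI/SfiI recognition site, also
#' considering junctions with the flanking test-segment bases. Deterministic
#' given `seed`.
#'
#' @param core DNA string of length `params$core_length`.
#' @param params a [design_params()] object.
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @param left_context,right_context test-segment bases immediately flanking
#'   the core (junction constraint checking).
#' @param variant_id label used in error messages.
#' @return the scrambled core (character scalar).
#' @export
scramble_core <- function(core, params = design_params(), seed = NULL,
                          left_context = "", right_context = "",
                          variant_id = "<core>") {
  assert_dna(core, "core")
  if (nchar(core) != params$core_length) {
    stop(sprintf("core must have length %d", params$core_length), call. = FALSE)
  }
  bases <- strsplit(core, "", fixed = TRUE)[[1]]
  with_seed_if(seed, {
    for (i in seq_len(params$max_attempts)) {
      cand <- paste(sample(bases), collapse = "")
      if (!violates_in_context(cand, left_context, right_context, params)) {
        return(cand)
      }
    }
    stop(sprintf(
      "no constraint-satisfying permutation of the core found for %s after %d attempts",
      variant_id, params$max_attempts), call. = FALSE)
  })
}

#' Generate constrained random barcodes
#'
#' Draws `n` distinct `tag_length`-nt barcodes uniformly from the sequences
#' that contain no homopolymer run longer than `params$max_homopolymer` and no
#' KpnI/XbaI/SfiI site, with constraints also checked across the junctions
#' with the fixed linker and primer context in which the barcode is embedded.
#' Deterministic given `seed`.
#'
#' @param n number of barcodes.
#' @param params a [design_params()] object.
#' @param seed optional integer seed.
#' @param exclude barcodes already in use (never re-emitted).
#' @return character vector of `n` distinct barcodes.
#' @export
generate_tags <- function(n, params = design_params(), seed = NULL,
                          exclude = character()) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  with_seed_if(seed, {
    tags <- character(0)
    attempts <- 0L
    while (length(tags) < n) {
      batch <- max(2L * (n - length(tags)), 1000L)
      cand <- random_dna(batch, params$tag_length)
      cand <- cand[tag_valid(cand, params)]
      tags <- c(tags, setdiff(unique(cand), c(tags, exclude)))
      attempts <- attempts + 1L
      if (attempts > 1000L) {
        stop(sprintf("could not generate %d valid distinct barcodes of length %d",
                     n, params$tag_length), call. = FALSE)
      }
    }
    tags[seq_len(n)]
  })
}

# Forward test segments (risk, protective, scrambled) for one variant.
# The window is sized on the longer (insertion) allele; the shorter allele's
# segment is left correspondingly shorter.  RNG is consumed for the scramble.
build_test_segments <- function(variant, params) {
  risk <- toupper(variant$risk_allele)
  prot <- toupper(variant$protective_allele)
  ref <- toupper(variant$reference_allele)
  assert_dna(c(risk, prot, ref), paste0("alleles of ", variant$variant_id))
  if (risk == prot) {
    stop("risk and protective alleles are identical for ", variant$variant_id,
         call. = FALSE)
  }
  left_need <- params$variant_offset - 1L
  len_max <- max(nchar(risk), nchar(prot))
  right_need <- params$test_length - left_need - len_max
  if (right_need < 0L) stop("allele too long for the test window", call. = FALSE)
  lf <- toupper(variant$left_flank)
  rf <- toupper(variant$right_flank)
  if (nchar(lf) < left_need || nchar(rf) < right_need) {
    stop(sprintf("flanks of %s too short for a %d-nt window (need %d left, %d right)",
                 variant$variant_id, params$test_length, left_need, right_need),
         call. = FALSE)
  }
  left <- substr(lf, nchar(lf) - left_need + 1L, nchar(lf))
  right <- substr(rf, 1L, right_need)
  assert_dna(c(left, right), paste0("flanks of ", variant$variant_id))

  seg <- function(allele) paste0(left, allele, right)
  seg_ref <- seg(ref)
  half <- (params$core_length - 1L) %/% 2L
  core_start <- params$variant_offset - half
  core_end <- core_start + params$core_length - 1L
  if (core_start < 1L || core_end > nchar(seg_ref)) {
    stop("reference segment too short to host the scrambled core for ",
         variant$variant_id, call. = FALSE)
  }
  core <- substr(seg_ref, core_start, core_end)
  scr_core <- scramble_core(core, params,
                            left_context = substr(seg_ref, 1L, core_start - 1L),
                            right_context = substr(seg_ref, core_end + 1L,
                                                   nchar(seg_ref)),
                            variant_id = variant$variant_id)
  scrambled <- paste0(substr(seg_ref, 1L, core_start - 1L), scr_core,
                      substr(seg_ref, core_end + 1L, nchar(seg_ref)))
  list(risk = seg(risk), protective = seg(prot), scrambled = scrambled)
}

#' Design all oligo records for one variant
#'
#' Emits `(risk, protective, scrambled) x (forward, reverse) x
#' tags_per_sequence` records: 60 under default parameters. The variant is
#' placed with its first base at `params$variant_offset` of the test window;
#' the reverse-orientation segment is the reverse complement of the forward
#' one; the scrambled class permutes the core of the reference-allele segment.
#' Test segments containing a cloning site are emitted with `site_flag = TRUE`
#' rather than excluded.
#'
#' @param variant one-row data frame (or list) with `variant_id`,
#'   `risk_allele`, `protective_allele`, `reference_allele`, `left_flank`,
#'   `right_flank`.
#' @param params a [design_params()] object.
#' @param tags character vector of at least `6 * tags_per_sequence` unused
#'   barcodes.
#' @param library_ids library membership recorded on each record
#'   (`";"`-separated when the variant is synthesised in several libraries).
#' @return tibble of oligo records.
#' @export
design_variant_entries <- function(variant, params = design_params(), tags,
                                   library_ids = "lib1") {
  segs <- build_test_segments(variant, params)
  need <- 6L * params$tags_per_sequence
  if (length(tags) < need) {
    stop(sprintf("need %d unassigned tags, got %d", need, length(tags)),
         call. = FALSE)
  }
  classes <- rep(names(segs), each = 2L)
  orients <- rep(c("forward", "reverse"), times = 3L)
  fwd <- unlist(segs, use.names = FALSE)[rep(1:3, each = 2L)]
  seq_out <- ifelse(orients == "reverse", revcomp(fwd), fwd)
  k <- params$tags_per_sequence
  idx <- rep(seq_len(6L), each = k)
  tb <- tibble(
    oligo_id = sprintf("%s|%s|%s|t%02d", variant$variant_id, classes[idx],
                       substr(orients[idx], 1, 3), rep(seq_len(k), times = 6L)),
    variant_id = variant$variant_id,
    seq_class = classes[idx],
    orientation = orients[idx],
    barcode = tags[seq_len(need)],
    test_segment = seq_out[idx],
    library_ids = paste(library_ids, collapse = ";")
  )
  tb$full_sequence <- paste0(MPRA_PRIMER_5, tb$test_segment, MPRA_LINKER,
                             tb$barcode, MPRA_PRIMER_3)
  tb$site_flag <- segment_site_flag(tb$test_segment)
  tb
}

#' Build a complete MPRA design manifest
#'
#' Generates one global pool of constrained barcodes (one unique barcode per
#' oligo) and assembles records for every variant. A variant listed in several
#' libraries keeps the same barcode-to-sequence assignment in each, so the
#' unique-sequence count is `60 * n_variants` under default parameters.
#' Byte-identical output for the same inputs and seed.
#'
#' @param variants tibble of variant specifications (see
#'   [design_variant_entries()] for required columns); an optional
#'   `library_ids` column (`";"`-separated) records multi-library membership.
#' @param params a [design_params()] object.
#' @param seed integer seed driving barcode generation and core scrambling.
#' @return an object of class `mpra_design`: a list with `oligos` (tibble of
#'   records), `params`, and `seed`.
#' @export
build_library <- function(variants, params = design_params(), seed = 1L) {
  variants <- as_tibble(variants)
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant_id in `variants`", call. = FALSE)
  }
  n <- nrow(variants)
  per <- 6L * params$tags_per_sequence
  oligos <- if (n == 0L) {
    tibble(oligo_id = character(), variant_id = character(),
           seq_class = character(), orientation = character(),
           barcode = character(), test_segment = character(),
           library_ids = character(), full_sequence = character(),
           site_flag = logical())
  } else {
    withr::with_seed(as.integer(seed), {
      pool <- generate_tags(n * per, params)
      libs <- if ("library_ids" %in% names(variants)) {
        variants$library_ids
      } else rep("lib1", n)
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        rows[[i]] <- design_variant_entries(
          variants[i, ], params,
          tags = pool[((i - 1L) * per + 1L):(i * per)],
          library_ids = libs[i]
        )
      }
      bind_rows(rows)
    })
  }
  structure(list(oligos = oligos, params = params, seed = as.integer(seed)),
            class = "mpra_design")
}

#' @export
print.mpra_design <- function(x, ...) {
  cat(sprintf("MPRA design: %d oligos, %d variants, %d unique sequences (seed %d)\n",
              nrow(x$oligos), length(unique(x$oligos$variant_id)),
              length(unique(x$oligos$full_sequence)), x$seed))
  invisible(x)
}

#' Barcode index of a design manifest
#'
#' @param manifest an `mpra_design` object.
#' @return tibble mapping each barcode to its variant, sequence class,
#'   orientation and library membership (a bijection onto oligo records).
#' @export
barcode_index <- function(manifest) {
  stopifnot(inherits(manifest, "mpra_design"))
  manifest$oligos[, c("barcode", "variant_id", "seq_class", "orientation",
                      "library_ids")]
}

#' Write a design manifest to disk
#'
#' Emits the oligo FASTA (ids are oligo ids), the manifest table and the
#' barcode index as tab-separated files.
#'
#' @param manifest an `mpra_design` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_design <- function(manifest, dir) {
  stopifnot(inherits(manifest, "mpra_design"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "oligos.fasta")
  seqs <- Biostrings::DNAStringSet(manifest$oligos$full_sequence)
  names(seqs) <- manifest$oligos$oligo_id
  Biostrings::writeXStringSet(seqs, fa)
  man <- file.path(dir, "design_manifest.tsv")
  write.table(manifest$oligos, man, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- file.path(dir, "barcode_index.tsv")
  write.table(barcode_index(manifest), idx, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fa, manifest = man, index = idx))
}
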