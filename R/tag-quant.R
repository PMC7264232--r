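# Barcode counting from FASTQ, library verification, TPM normalisation,
# filtering, and per-tag activity observations.

#' Count barcode tags in a FASTQ file
#'
#' A read is assigned to a barcode if and only if its first
#' `nchar(barcode)` bases equal a known barcode **and** the following 20 bases
#' equal the fixed downstream context, both as exact matches. Everything else
#' is counted as unassigned.
#'
#' @param fastq path to a FASTQ(.gz) file, or a character vector of read
#'   sequences.
#' @param barcode_index an `mpra_design` manifest, a data frame with a
#'   `barcode` column, or a character vector of barcodes.
#' @param context fixed sequence expected immediately after the barcode.
#' @return list with `counts` (named integer vector over all barcodes in the
#'   index), `n_reads`, `n_assigned`, `n_unassigned`, and `assignment_rate`.
#' @export
count_tags <- function(fastq, barcode_index, context = MPRA_READ_CONTEXT) {
  barcodes <- if (inherits(barcode_index, "mpra_design")) {
    barcode_index$oligos$barcode
  } else if (is.data.frame(barcode_index)) {
    barcode_index$barcode
  } else {
    as.character(barcode_index)
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcodes in the index", call. = FALSE)
  }
  reads <- if (length(fastq) == 1L && file.exists(fastq)) {
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  } else {
    as.character(fastq)
  }
  blen <- nchar(barcodes[1])
  counts <- setNames(integer(length(barcodes)), barcodes)
  if (length(reads) == 0L) {
    warning("no reads; returning empty counts")
    return(list(counts = counts, n_reads = 0L, n_assigned = 0L,
                n_unassigned = 0L, assignment_rate = NA_real_))
  }
  bc <- substr(reads, 1L, blen)
  ctx <- substr(reads, blen + 1L, blen + nchar(context))
  hit <- ctx == context & bc %in% barcodes
  tab <- table(factor(bc[hit], levels = barcodes))
  counts[] <- as.integer(tab)
  n_assigned <- sum(hit)
  list(counts = counts, n_reads = length(reads), n_assigned = n_assigned,
       n_unassigned = length(reads) - n_assigned,
       assignment_rate = n_assigned / length(reads))
}

#' Count tags for every sample in a sample sheet
#'
#' @param sample_sheet tibble with `sample_id` and `fastq_path` columns.
#' @param barcode_index see [count_tags()].
#' @param context see [count_tags()].
#' @return list with `counts` (barcode x sample integer matrix) and `summary`
#'   (per-sample read totals and assignment rates).
#' @export
count_samples <- function(sample_sheet, barcode_index,
                          context = MPRA_READ_CONTEXT) {
  res <- lapply(sample_sheet$fastq_path, count_tags,
                barcode_index = barcode_index, context = context)
  counts <- vapply(res, function(r) r$counts, res[[1]]$counts)
  colnames(counts) <- sample_sheet$sample_id
  summ <- tibble(
    sample_id = sample_sheet$sample_id,
    n_reads = vapply(res, `[[`, integer(1), "n_reads"),
    n_assigned = vapply(res, `[[`, integer(1), "n_assigned"),
    assignment_rate = vapply(res, `[[`, numeric(1), "assignment_rate")
  )
  list(counts = counts, summary = summ)
}

#' Verify library representation
#'
#' Fraction of designed oligos detected with at least `min_reads` reads in a
#' verification or DNA-input sample, overall and per library and orientation.
#'
#' @param counts named count vector (from [count_tags()]) or a barcode x
#'   sample matrix (summed over columns).
#' @param manifest an `mpra_design` object.
#' @param min_reads detection threshold.
#' @return tibble of coverage fractions.
#' @export
verify_library <- function(counts, manifest, min_reads = 10L) {
  stopifnot(inherits(manifest, "mpra_design"))
  if (is.matrix(counts)) counts <- rowSums(counts)
  ol <- manifest$oligos
  cov <- counts[ol$barcode]
  cov[is.na(cov)] <- 0
  det <- cov >= min_reads
  per <- as_tibble(expand.grid(
    library_id = unique(unlist(strsplit(ol$library_ids, ";", fixed = TRUE))),
    orientation = unique(ol$orientation), stringsAsFactors = FALSE))
  per$fraction_detected <- mapply(function(l, o) {
    sel <- grepl(l, ol$library_ids, fixed = TRUE) & ol$orientation == o
    mean(det[sel])
  }, per$library_id, per$orientation, USE.NAMES = FALSE)
  overall <- tibble(library_id = "all", orientation = "all",
                    fraction_detected = mean(det))
  bind_rows(overall, per)
}

#' Tag counts per million matched reads
#'
#' Divides each tag count by the sample's total matched count over one
#' million, so each sample's TPM column sums to 1e6.
#'
#' @param counts non-negative count vector or barcode x sample matrix.
#' @return object of the same shape holding TPM values.
#' @export
compute_tpm <- function(counts) {
  if (is.matrix(counts)) {
    tot <- colSums(counts)
    if (any(tot == 0)) {
      stop("sample(s) with zero total counts: ",
           paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
    }
    sweep(counts, 2L, tot / 1e6, "/")
  } else {
    tot <- sum(counts)
    if (tot == 0) stop("all-zero sample", call. = FALSE)
    counts / (tot / 1e6)
  }
}

#' Filter tags by count and input abundance
#'
#' For each RNA sample (one per transfection), a tag is retained only if its
#' raw count is at least `min_count` in both the RNA sample and its paired
#' DNA-input sample, and its DNA-input TPM is at least `min_dna_tpm` (low
#' input abundance otherwise dominates the RNA/DNA ratio). Defaults implement
#' "10 tag counts or lower excluded" and "DNA TPM < 6 removed".
#'
#' @param counts barcode x sample raw count matrix.
#' @param sample_sheet tibble with `sample_id`, `material` ("DNA"/"RNA"), and
#'   for RNA samples `dna_sample_id` naming the paired input.
#' @param min_count minimum raw count (both materials).
#' @param min_dna_tpm minimum DNA-input TPM.
#' @return list with `keep` (barcode x RNA-sample logical matrix) and
#'   `retention` (per-sample detected/retained tallies).
#' @export
filter_tags <- function(counts, sample_sheet, min_count = 11L,
                        min_dna_tpm = 6) {
  tpm <- compute_tpm(counts)
  rna <- sample_sheet[sample_sheet$material == "RNA", ]
  keep <- matrix(FALSE, nrow(counts), nrow(rna),
                 dimnames = list(rownames(counts), rna$sample_id))
  for (j in seq_len(nrow(rna))) {
    r <- rna$sample_id[j]
    d <- rna$dna_sample_id[j]
    if (!d %in% colnames(counts)) {
      stop("paired DNA sample missing from counts: ", d, call. = FALSE)
    }
    keep[, j] <- counts[, r] >= min_count & counts[, d] >= min_count &
      tpm[, d] >= min_dna_tpm
  }
  n_det <- unname(colSums(counts[, rna$sample_id, drop = FALSE] > 0))
  n_ret <- unname(colSums(keep))
  retention <- tibble(
    sample_id = rna$sample_id,
    n_detected = n_det,
    n_retained = n_ret,
    fraction_retained = n_ret / pmax(n_det, 1L)
  )
  list(keep = keep, retention = retention)
}

#' Per-tag log2(RNA TPM / DNA TPM) activity observations
#'
#' One observation per retained (tag, transfection) pair, annotated with the
#' design (variant, sequence class, orientation) and the sample sheet
#' (transfection, cell line, promoter, library).
#'
#' @param counts barcode x sample raw count matrix.
#' @param keep logical barcode x RNA-sample matrix from [filter_tags()].
#' @param sample_sheet see [filter_tags()]; RNA rows must also carry
#'   `transfection_id`, `cell_line`, `promoter`, `library_id`.
#' @param manifest an `mpra_design` object.
#' @return tibble of activity observations.
#' @export
compute_log_ratios <- function(counts, keep, sample_sheet, manifest) {
  stopifnot(inherits(manifest, "mpra_design"))
  tpm <- compute_tpm(counts)
  rna <- sample_sheet[sample_sheet$material == "RNA", ]
  idx <- manifest$oligos
  miss <- setdiff(rownames(counts), idx$barcode)
  if (length(miss) > 0L) {
    stop("count matrix contains barcode(s) absent from the manifest: ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  }
  m <- match(rownames(counts), idx$barcode)
  out <- vector("list", nrow(rna))
  for (j in seq_len(nrow(rna))) {
    sel <- keep[, rna$sample_id[j]]
    if (!any(sel)) next
    lr <- log2(tpm[sel, rna$sample_id[j]] / tpm[sel, rna$dna_sample_id[j]])
    out[[j]] <- tibble(
      barcode = rownames(counts)[sel],
      variant_id = idx$variant_id[m[sel]],
      seq_class = idx$seq_class[m[sel]],
      orientation = idx$orientation[m[sel]],
      transfection_id = rna$transfection_id[j],
      cell_line = rna$cell_line[j],
      promoter = rna$promoter[j],
      library_id = rna$library_id[j],
      log2_ratio = unname(lr)
    )
  }
  bind_rows(out)
}

#' Counts to filtered activity observations in one call
#'
#' Convenience wrapper chaining [filter_tags()] and [compute_log_ratios()];
#' the retention report is attached as attribute `"retention"`.
#'
#' @inheritParams compute_log_ratios
#' @inheritParams filter_tags
#' @return tibble of activity observations.
#' @export
mpra_observations <- function(counts, sample_sheet, manifest,
                              min_count = 11L, min_dna_tpm = 6) {
  flt <- filter_tags(counts, sample_sheet, min_count, min_dna_tpm)
  obs <- compute_log_ratios(counts, flt$keep, sample_sheet, manifest)
  attr(obs, "retention") <- flt$retention
  obs
}

#' Pairwise replicate correlation of activity observations
#'
#' Pearson correlation of per-barcode log2 TPM ratios between every pair of
#' transfections, over the barcodes retained in both members of a pair.
#'
#' @param obs observation tibble (see [mpra_observations()]).
#' @return symmetric correlation matrix; entries with fewer than two shared
#'   tags are `NA`.
#' @export
replicate_correlation <- function(obs) {
  tr <- sort(unique(obs$transfection_id))
  if (length(tr) < 2L) stop("need >= 2 transfections", call. = FALSE)
  bc <- sort(unique(obs$barcode))
  wide <- matrix(NA_real_, length(bc), length(tr),
                 dimnames = list(bc, tr))
  wide[cbind(match(obs$barcode, bc), match(obs$transfection_id, tr))] <-
    obs$log2_ratio
  suppressWarnings(cor(wide, use = "pairwise.complete.obs"))
}
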