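# Oligo skeleton constants and design-parameter container.
#
# The synthesised construct is
#   5'-<primer5>-<145 nt test segment>-<KpnI+XbaI linker>-<10 nt tag>-<primer3>-3'
# so a full-length record is 16 + 145 + 12 + 10 + 17 = 200 nt.

MPRA_PRIMER_5 <- "ACTGGCCGCTTCACTG"
MPRA_LINKER <- "GGTACCTCTAGA"
MPRA_PRIMER_3 <- "AGATCGGAAGAGCGTCG"

#' Sequencing-read context downstream of the barcode
#'
#' In tag-count sequencing reads, the 10-nt barcode is followed by this fixed
#' 20-nt context (an XbaI site plus the 3' end of the luciferase ORF); a read
#' is assigned only if both match exactly.
#'
#' @export
MPRA_READ_CONTEXT <- "TCTAGAATTATTACACGGCG"

# Enzyme recognition patterns excluded from barcodes and scrambled cores.
FORBIDDEN_SITE_PATTERNS <- c(
  KpnI = "GGTACC",
  XbaI = "TCTAGA",
  SfiI = "GGCC[ACGT]{5}GGCC"
)

#' Design parameters for MPRA oligo construction
#'
#' Defaults reproduce the standard design: a 145-nt test window with the
#' variant's first base at position 73 (centred for a SNV), a 21-nt scrambled
#' core, 10-nt barcodes with 10 tags per unique sequence, homopolymer runs
#' capped at 3, and KpnI/XbaI/SfiI recognition sites excluded from barcodes
#' and scrambled cores (they are the cloning sites of the vector skeleton).
#'
#' @param test_length length of the test segment in nt (sized on the longer
#'   allele for indels).
#' @param core_length odd length of the scrambled core around the variant.
#' @param tag_length barcode length in nt.
#' @param tags_per_sequence barcodes synthesised per unique test sequence.
#' @param max_homopolymer longest allowed single-base run in barcodes and
#'   scrambled cores (runs of `max_homopolymer + 1` are rejected).
#' @param variant_offset 1-based position of the variant's first base within
#'   the test window.
#' @param max_attempts bound on rejection-sampling attempts before a design
#'   error is raised.
#' @return an object of class `design_params`.
#' @export
#' @examples
#' p <- design_params()
#' p$test_length
design_params <- function(test_length = 145L, core_length = 21L,
                          tag_length = 10L, tags_per_sequence = 10L,
                          max_homopolymer = 3L, variant_offset = 73L,
                          max_attempts = 1e5L) {
  core_length <- as.integer(core_length)
  if (core_length %% 2L != 1L) stop("core_length must be odd", call. = FALSE)
  if (test_length < core_length) {
    stop("test_length must be >= core_length", call. = FALSE)
  }
  structure(list(
    test_length = as.integer(test_length),
    core_length = core_length,
    tag_length = as.integer(tag_length),
    tags_per_sequence = as.integer(tags_per_sequence),
    max_homopolymer = as.integer(max_homopolymer),
    variant_offset = as.integer(variant_offset),
    forbidden_sites = FORBIDDEN_SITE_PATTERNS,
    max_attempts = as.integer(max_attempts)
  ), class = "design_params")
}

homopolymer_pattern <- function(max_run) {
  sprintf("([ACGT])\\1{%d,}", max_run)
}

# All (possibly overlapping) match intervals of `pattern` in `x` (scalar).
pattern_hits <- function(x, pattern, len = NULL) {
  if (is.null(len)) {
    m <- gregexpr(pattern, x, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    cbind(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
  } else {
    # fixed-length patterns: lookahead finds overlapping occurrences too
    m <- gregexpr(sprintf("(?=%s)", pattern), x, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    cbind(start = as.integer(m), end = as.integer(m) + len - 1L)
  }
}

# Does `variable`, placed between `left` and `right`, create a homopolymer run
# or a forbidden restriction site that overlaps the variable segment?  The
# fixed skeleton intentionally contains KpnI/XbaI sites, so only matches that
# touch the variable bases count.  Scalar in `variable`.
violates_in_context <- function(variable, left, right, params) {
  # windows wide enough for the longest pattern (SfiI, 13 nt)
  lw <- substr(left, max(1L, nchar(left) - 11L), nchar(left))
  rw <- substr(right, 1L, 12L)
  w <- paste0(lw, variable, rw)
  v_start <- nchar(lw) + 1L
  v_end <- nchar(lw) + nchar(variable)
  overlaps <- function(hits) {
    !is.null(hits) && any(hits[, "start"] <= v_end & hits[, "end"] >= v_start)
  }
  hp <- pattern_hits(w, homopolymer_pattern(params$max_homopolymer))
  if (overlaps(hp)) return(TRUE)
  for (p in params$forbidden_sites) {
    len <- if (grepl("\\{5\\}", p)) 13L else 6L
    if (overlaps(pattern_hits(w, p, len))) return(TRUE)
  }
  FALSE
}

# Vectorised constraint check for candidate barcodes in the fixed
# linker/primer context.  The trimmed windows contain no homopolymer run of
# length > max_homopolymer and no forbidden-site match on their own, so any
# match in the windowed string necessarily involves tag bases.
tag_valid <- function(tags, params) {
  hp <- homopolymer_pattern(params$max_homopolymer)
  l3 <- substr(MPRA_LINKER, nchar(MPRA_LINKER) - params$max_homopolymer + 1L,
               nchar(MPRA_LINKER))
  r3 <- substr(MPRA_PRIMER_3, 1L, params$max_homopolymer)
  ok <- !grepl(hp, paste0(l3, tags, r3), perl = TRUE)
  l5 <- substr(MPRA_LINKER, nchar(MPRA_LINKER) - 4L, nchar(MPRA_LINKER))
  r5 <- substr(MPRA_PRIMER_3, 1L, 5L)
  ok <- ok & !grepl("GGTACC|TCTAGA", paste0(l5, tags, r5))
  r12 <- substr(MPRA_PRIMER_3, 1L, 12L)
  ok & !grepl("GGCC[ACGT]{5}GGCC", paste0(MPRA_LINKER, tags, r12))
}

# Forbidden cloning site anywhere in a test segment (QC flag, not exclusion);
# junctions with the fixed skeleton are included.
segment_site_flag <- function(segments) {
  l5 <- substr(MPRA_PRIMER_5, nchar(MPRA_PRIMER_5) - 4L, nchar(MPRA_PRIMER_5))
  r5 <- substr(MPRA_LINKER, 1L, 5L)
  w <- paste0(l5, segments, r5)
  flag <- grepl("GGTACC|TCTAGA", w)
  w13 <- paste0(substr(MPRA_PRIMER_5, 5L, 16L), segments, MPRA_LINKER)
  flag | grepl("GGCC[ACGT]{5}GGCC", w13)
}
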