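# Oligo library construction: variant selection, scrambling, barcodes,
# full-record assembly.

test_that("variant selection honours containment, boundaries and the rule", {
  v <- dplyr::bind_rows(
    toy_variant("in_peak"), toy_variant("boundary"), toy_variant("low_ld", r2 = 0.2)
  )
  v$pos <- c(100L, 89L, 100L)
  v$ld_r2_with_lead <- c(0.5, 0.5, 0.2)
  tracks <- list(DHS = data.frame(chrom = "chr1", start = 90L, end = 110L))
  sel <- select_candidate_variants(v, tracks, "DHS")
  # pos 100 (0-based 99) is inside [90,110); pos 89 (0-based 88) is not
  expect_identical(sel$variant_id, "in_peak")
  expect_error(select_candidate_variants(v, tracks, "FAIRE"), "unknown track")
})

test_that("negative controls pass only when whitelisted; odd chromosomes warn", {
  v <- dplyr::bind_rows(toy_variant("neg", neg = TRUE), toy_variant("pos"))
  v$pos <- c(100L, 100L)
  tracks <- list(DHS = data.frame(chrom = "chr1", start = 90L, end = 110L))
  expect_identical(select_candidate_variants(v, tracks, "DHS")$variant_id, "pos")
  sel <- select_candidate_variants(v, tracks, "DHS", keep_negative_controls = TRUE)
  expect_setequal(sel$variant_id, c("neg", "pos"))
  v2 <- toy_variant("offchrom")
  v2$chrom <- "chrX"
  expect_warning(sel2 <- select_candidate_variants(v2, tracks, "DHS"),
                 "absent from all tracks")
  expect_identical(nrow(sel2), 0L)
})

test_that("selection agrees with a brute-force interval scan with a compound rule", {
  withr::with_seed(11, {
    n <- 20
    v <- dplyr::bind_rows(lapply(seq_len(n), function(i) toy_variant(paste0("v", i))))
    v$chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    v$pos <- sample.int(1000L, n)
    v$ld_r2_with_lead <- runif(n)
    mk_track <- function(m) {
      st <- sample.int(1000L, m)
      data.frame(chrom = sample(c("chr1", "chr2"), m, replace = TRUE),
                 start = st, end = st + sample.int(50L, m))
    }
    tracks <- list(A = mk_track(30), B = mk_track(30), C = mk_track(30))
    sel <- select_candidate_variants(v, tracks, "A | (B & C)", r2_threshold = 0.4)
    expected <- vapply(seq_len(n), function(i) {
      a <- oracle_overlaps_track(v$chrom[i], v$pos[i], tracks$A)
      b <- oracle_overlaps_track(v$chrom[i], v$pos[i], tracks$B)
      cc <- oracle_overlaps_track(v$chrom[i], v$pos[i], tracks$C)
      v$ld_r2_with_lead[i] >= 0.4 && (a || (b && cc))
    }, logical(1))
    expect_setequal(sel$variant_id, v$variant_id[expected])
  })
})

test_that("scrambled cores are constrained permutations and fail when impossible", {
  p <- design_params()
  expect_error(scramble_core(strrep("A", 21), p, seed = 1),
               "no constraint-satisfying permutation")
  withr::with_seed(5, {
    for (i in 1:20) {
      core <- rand_flank(21)
      left <- rand_flank(15); right <- rand_flank(15)
      out <- scramble_core(core, p, left_context = left, right_context = right)
      expect_identical(sort(strsplit(out, "")[[1]]), sort(strsplit(core, "")[[1]]))
      expect_false(oracle_violates(out, left, right))
    }
  })
  # deterministic given seed
  core <- "ACGTACGTACGTACGTACGTA"
  s1 <- scramble_core(core, p, seed = 1)
  expect_identical(s1, scramble_core(core, p, seed = 1))
  expect_false(oracle_violates(s1))
})

test_that("generated barcodes are unique, deterministic and constraint-free in context", {
  p <- design_params()
  t1 <- generate_tags(50, p, seed = 3)
  expect_identical(t1, generate_tags(50, p, seed = 3))
  expect_identical(generate_tags(1, p, seed = 9), generate_tags(1, p, seed = 9))
  expect_false(anyDuplicated(t1) > 0)
  expect_true(all(nchar(t1) == 10L))
  linker <- "GGTACCTCTAGA"; primer3 <- "AGATCGGAAGAGCGTCG"
  for (tg in t1) expect_false(oracle_violates(tg, linker, primer3))
  expect_error(generate_tags(0, p), "n must be >= 1")
})

test_that("a full-size barcode pool (36,660 tags) is generated distinct and valid", {
  p <- design_params()
  pool <- generate_tags(36660, p, seed = 21)
  expect_length(pool, 36660L)
  expect_identical(anyDuplicated(pool), 0L)
  spot <- pool[seq(1, 36660, length.out = 200)]
  for (tg in spot) expect_false(oracle_violates(tg, "GGTACCTCTAGA", "AGATCGGAAGAGCGTCG"))
})

test_that("one SNV yields 60 records with the fixed skeleton and reverse complements", {
  v <- toy_variant()
  man <- build_library(v, seed = 4)
  ol <- man$oligos
  expect_identical(nrow(ol), 60L)
  expect_identical(length(unique(ol$full_sequence)), 60L)
  expect_true(all(nchar(ol$full_sequence) == 200L))
  expect_true(all(nchar(ol$test_segment) == 145L))
  expect_true(all(grepl(
    "^ACTGGCCGCTTCACTG[ACGT]{145}GGTACCTCTAGA[ACGT]{10}AGATCGGAAGAGCGTCG$",
    ol$full_sequence)))
  expect_identical(anyDuplicated(ol$barcode), 0L)
  # reverse segments are reverse complements of the forward ones, per cell
  for (cl in c("risk", "protective", "scrambled")) {
    fwd <- unique(ol$test_segment[ol$seq_class == cl & ol$orientation == "forward"])
    rev <- unique(ol$test_segment[ol$seq_class == cl & ol$orientation == "reverse"])
    expect_identical(rev, revcomp(fwd))
  }
  # scrambled core is an exact permutation of the reference core
  fwd_ref <- unique(ol$test_segment[ol$seq_class == "risk" & ol$orientation == "forward"])
  fwd_scr <- unique(ol$test_segment[ol$seq_class == "scrambled" & ol$orientation == "forward"])
  core_ref <- substr(fwd_ref, 63, 83)
  core_scr <- substr(fwd_scr, 63, 83)
  expect_identical(substr(fwd_ref, 1, 62), substr(fwd_scr, 1, 62))
  expect_identical(substr(fwd_ref, 84, 145), substr(fwd_scr, 84, 145))
  expect_identical(sort(strsplit(core_scr, "")[[1]]), sort(strsplit(core_ref, "")[[1]]))
})

test_that("allele windows centre the variant and size indel records on the insertion allele", {
  v <- toy_variant(risk = "ACT", protective = "A", reference = "ACT")
  man <- build_library(v, seed = 8)
  ol <- man$oligos
  ins <- ol[ol$seq_class == "risk", ]
  del <- ol[ol$seq_class == "protective", ]
  expect_true(all(nchar(ins$test_segment) == 145L))
  expect_true(all(nchar(del$test_segment) == 143L))
  expect_true(all(nchar(del$full_sequence) == 198L))
  # SNV risk/protective segments differ exactly at position 73
  v2 <- toy_variant("v2", risk = "G", protective = "T", reference = "G")
  ol2 <- build_library(v2, seed = 8)$oligos
  r <- unique(ol2$test_segment[ol2$seq_class == "risk" & ol2$orientation == "forward"])
  q <- unique(ol2$test_segment[ol2$seq_class == "protective" & ol2$orientation == "forward"])
  diffs <- which(strsplit(r, "")[[1]] != strsplit(q, "")[[1]])
  expect_identical(diffs, 73L)
  expect_identical(substr(r, 73, 73), "G")
  expect_identical(substr(q, 73, 73), "T")
})

test_that("cloning sites arising from genomic sequence flag but do not drop records", {
  left <- paste0(rand_flank(60), "GGTACC", rand_flank(20))
  v <- toy_variant(left = left)
  man <- build_library(v, seed = 2)
  expect_identical(nrow(man$oligos), 60L)
  expect_true(any(man$oligos$site_flag))
})

test_that("manifests are deterministic, reuse tags across libraries, and scale as 60 per variant", {
  v <- dplyr::bind_rows(
    toy_variant("a", libraries = "lib1;lib2"),
    toy_variant("b", libraries = "lib2")
  )
  m1 <- build_library(v, seed = 10)
  m2 <- build_library(v, seed = 10)
  expect_identical(m1$oligos, m2$oligos)
  expect_identical(nrow(m1$oligos), 120L)
  # the repeated variant keeps one barcode set shared by both libraries
  a <- m1$oligos[m1$oligos$variant_id == "a", ]
  expect_true(all(a$library_ids == "lib1;lib2"))
  expect_identical(anyDuplicated(m1$oligos$barcode), 0L)
  expect_error(build_library(dplyr::bind_rows(toy_variant("x"), toy_variant("x"))),
               "duplicate variant_id")
  empty <- build_library(toy_variant()[0, ])
  expect_identical(nrow(empty$oligos), 0L)
})

test_that("design files round-trip through disk", {
  v <- toy_variant()
  man <- build_library(v, seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_design(man, dir)
  fa <- Biostrings::readDNAStringSet(paths["fasta"])
  expect_identical(length(fa), 60L)
  expect_identical(unname(as.character(fa)), man$oligos$full_sequence)
  idx <- read.delim(paths["index"])
  expect_identical(idx$barcode, man$oligos$barcode)
})
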