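test_that("mapper equals brute-force ungapped search with exact seed", {
  set.seed(55)
  genome <- c(g1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                         collapse = ""))
  idx <- build_index(genome, 18L)
  params <- mapping_params()
  reads <- character(120)
  for (i in seq_along(reads)) {
    L <- sample(18:26, 1)
    p <- sample(2000 - L, 1)
    s <- substring(genome, p, p + L - 1L)
    if (i %% 3 == 0) {                      # plant a tail substitution
      q <- sample(19:L, 1)
      substring(s, q, q) <- setdiff(c("A", "C", "G", "T"),
                                    substring(s, q, q))[1]
    }
    if (i %% 4 == 0) s <- revcomp(s)
    reads[i] <- s
  }
  col <- data.frame(sequence = unique(reads), count = 1L)
  got <- map_reads(col, idx, params, max_mismatches = 1L)
  for (s in col$sequence) {
    want <- oracle_map_read(s, genome, 18L, 1L, params$max_hits)
    sub <- got[got$sequence == s, c("ref_id", "pos", "strand", "mismatches")]
    if (is.null(want)) {
      expect_equal(nrow(sub), 0L)
    } else {
      o <- function(d) d[order(d$ref_id, d$pos, d$strand), , drop = FALSE]
      expect_equal(unname(as.matrix(o(sub))), unname(as.matrix(o(want))),
                   info = s)
    }
  }
})

test_that("seed mismatches are rejected, tail mismatches counted", {
  set.seed(56)
  genome <- c(g1 = paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                         collapse = ""))
  idx <- build_index(genome, 18L)
  s <- substring(genome, 101, 122)          # unique 22-mer
  expect_equal(nrow(map_reads(data.frame(sequence = s, count = 1L), idx)), 1L)
  # substitution at read position 20 (outside the seed): mapped with 1 mm
  s20 <- s; substring(s20, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                              substring(s, 20, 20))[1]
  a <- map_reads(data.frame(sequence = s20, count = 1L), idx,
                 max_mismatches = 1L)
  expect_equal(nrow(a), 1L)
  expect_equal(a$mismatches, 1L)
  # same substitution at position 10 (inside the seed): unmapped
  s10 <- s; substring(s10, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                              substring(s, 10, 10))[1]
  expect_equal(nrow(map_reads(data.frame(sequence = s10, count = 1L), idx,
                              max_mismatches = 1L)), 0L)
  # reads shorter than the seed are unmapped
  a <- map_reads(data.frame(sequence = substring(s, 1, 15), count = 1L), idx)
  expect_equal(nrow(a), 0L)
  expect_equal(attr(a, "n_unmapped"), 1L)
})

test_that("reads at more than max_hits loci are discarded as multimappers", {
  set.seed(57)
  unit <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  spacers <- vapply(1:7, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""), "")
  genome6 <- c(g = paste0(paste0(spacers[1:6], unit, collapse = ""), spacers[7]))
  idx6 <- build_index(genome6, 18L)
  a <- map_reads(data.frame(sequence = unit, count = 3L), idx6)
  expect_equal(nrow(a), 0L)
  expect_equal(attr(a, "n_multimapper"), 1L)
  # at exactly five loci the read is kept everywhere
  genome5 <- c(g = paste0(paste0(spacers[1:5], unit, collapse = ""), spacers[7]))
  a5 <- map_reads(data.frame(sequence = unit, count = 3L),
                  build_index(genome5, 18L))
  expect_equal(nrow(a5), 5L)
})

test_that("miRNA counting enforces the 5'/3' positional tolerance lattice", {
  b <- tiny_precursor_bundle()
  pre <- b$precursors[["pre1"]]
  params <- mapping_params()
  for (d5 in 0:3) for (d3 in 0:6) {
    pos <- 10L - d5
    end <- 32L + d3
    aln <- aln_row(substring(pre, pos + 1L, end), "pre1", pos)
    cnt <- count_mirnas(aln, b$matures, params)
    expect_equal(unname(cnt["mat1"] > 0), d5 <= 2 && d3 <= 5,
                 info = sprintf("d5=%d d3=%d", d5, d3))
  }
  # exact mature interval counts
  aln <- aln_row(substring(pre, 11, 32), "pre1", 10L)
  expect_equal(unname(count_mirnas(aln, b$matures, params)["mat1"]), 1L)
  # relaxing tolerances never decreases counts (monotonicity)
  aln <- rbind(aln_row(substring(pre, 8, 37), "pre1", 7L),
               aln_row(substring(pre, 11, 32), "pre1", 10L, count = 2L))
  base <- sum(count_mirnas(aln, b$matures, params))
  wide <- sum(count_mirnas(aln, b$matures,
                           mapping_params(offset5 = 3L, offset3 = 6L)))
  expect_gte(wide, base)
})

test_that("isomiR NTA reclassification follows the templated continuation", {
  b <- tiny_precursor_bundle()
  pre <- b$precursors[["pre1"]]
  mature <- substring(pre, 11, 32)
  cont <- substring(pre, 33, 33)            # templated continuation base
  other <- setdiff(c("A", "C", "G", "T"), cont)[1]

  # non-templated 3' addition: mismatch reclassified, record retained
  iso <- quantify_isomirs(aln_row(paste0(mature, other), "pre1", 10L,
                                  mismatches = 1L),
                          b$matures, b)
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$nta, other)
  expect_equal(iso$n_snv, 0L)
  expect_equal(iso$variant_label, "iso_add3p:1")

  # templated extension: a 3' shift, no NTA
  iso <- quantify_isomirs(aln_row(paste0(mature, cont), "pre1", 10L),
                          b$matures, b)
  expect_equal(iso$nta, "")
  expect_equal(iso$shift3, 1L)
  expect_match(iso$variant_label, "iso_3p:\\+1")

  # canonical read: variant "NA"
  iso <- quantify_isomirs(aln_row(mature, "pre1", 10L), b$matures, b)
  expect_equal(iso$variant_label, "NA")

  # two internal substitutions exceed the post-reclassification cap
  m2 <- mature
  for (q in c(3L, 8L))
    substring(m2, q, q) <- setdiff(c("A", "C", "G", "T"),
                                   substring(m2, q, q))[1]
  iso <- quantify_isomirs(aln_row(m2, "pre1", 10L, mismatches = 2L),
                          b$matures, b)
  expect_equal(nrow(iso), 0L)
})

test_that("class counting uses only each read's lowest-mismatch alignments", {
  aln <- rbind(aln_row("ACGTACGTACGTACGTACGTAC", "featA", 0L, 0L, count = 4L),
               aln_row("ACGTACGTACGTACGTACGTAC", "featB", 0L, 1L, count = 4L))
  cnt <- count_class(aln, c("featA", "featB"))
  expect_equal(unname(cnt), c(4L, 0L))
  # equal-mismatch multimappers all count in full
  aln0 <- rbind(aln_row("ACGTACGTACGTACGTACGTAC", "featA", 0L, 0L, count = 4L),
                aln_row("ACGTACGTACGTACGTACGTAC", "featB", 0L, 0L, count = 4L))
  expect_equal(unname(count_class(aln0, c("featA", "featB"))), c(4L, 4L))
  # no qualifying alignments contribute nowhere
  expect_equal(sum(count_class(aln[0, ], c("featA", "featB"))), 0L)
})

test_that("miRGFF3 export round-trips and labels canonical reads NA", {
  # empty input: header-only document
  f <- tempfile(fileext = ".gff3")
  write_mirgff3(data.frame(), f)
  expect_true(all(startsWith(readLines(f), "#")))
  expect_equal(nrow(read_mirgff3(f)), 0L)

  set.seed(31)
  spec <- simulation_spec(seed = 31, n_samples = 1, n_mirnas = 15,
                          depth_per_sample = 3000, error_rate = 0.005)
  study <- simulate_study(spec, genome_len = 30000)
  res <- preprocess_sample(study$samples$sample01,
                           preprocess_config(adapter3 = spec$adapter))
  idx <- build_index(study$bundle$precursors, 18L)
  aln <- map_reads(res$collapsed, idx, max_mismatches = 2L)
  iso <- quantify_isomirs(aln, study$bundle$matures, study$bundle)
  expect_gt(nrow(iso), 20L)
  write_mirgff3(iso, f)
  back <- read_mirgff3(f)
  expect_equal(back$sequence, iso$sequence)
  expect_equal(back$variant_label, iso$variant_label)
  expect_equal(back$count, iso$count)
  expect_equal(back$pos, iso$pos)
  expect_equal(back$mature_id, iso$mature_id)
})

test_that("SAM ingestion keeps ungapped records and honours NM and counts", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:pre1\tLN:70",
    "r1_x5\t0\tpre1\t11\t255\t22M\t*\t0\t0\tACGTACGTACGTACGTACGTAC\t*\tNM:i:1",
    "r2\t16\tpre1\t1\t255\t10M\t*\t0\t0\tACGTACGTAC\t*\tNM:i:0",
    "r3\t0\tpre1\t1\t255\t5M2I5M\t*\t0\t0\tACGTACGTACGT\t*",     # gapped: skipped
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*"),                      # unmapped
    sam)
  aln <- read_sam_alignments(sam)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$count[1], 5L)
  expect_equal(aln$mismatches[1], 1L)
  expect_equal(aln$pos[1], 10L)
  expect_equal(aln$strand[2], "-")
  expect_equal(aln$sequence[2], revcomp("ACGTACGTAC"))
})
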