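test_that("adapter trimming handles exact, mismatched and absent adapters", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  cfg1 <- preprocess_config(adapter3 = adapter, max_adapter_edit_dist = 1)
  cfg0 <- preprocess_config(adapter3 = adapter, max_adapter_edit_dist = 0)

  # no occurrence: identity
  r <- list(sequence = "ACGTACGT", quality = rep(40L, 8))
  expect_false(trim_adapter(r, cfg1)$trimmed)
  expect_equal(trim_adapter(r, cfg1)$sequence, "ACGTACGT")

  # exact adapter after a 22-nt insert
  set.seed(5)
  insert <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  r <- list(sequence = paste0(insert, adapter), quality = rep(40L, 43))
  tr <- trim_adapter(r, cfg1)
  expect_true(tr$trimmed)
  expect_equal(tr$sequence, insert)
  expect_length(tr$quality, 22)

  # one substitution: trimmed at distance cap 1, untouched at cap 0
  mut <- adapter
  substring(mut, 4, 4) <- if (substring(mut, 4, 4) == "A") "C" else "A"
  r <- list(sequence = paste0(insert, mut), quality = rep(40L, 43))
  expect_true(trim_adapter(r, cfg1)$trimmed)
  expect_equal(trim_adapter(r, cfg1)$sequence, insert)
  expect_false(trim_adapter(r, cfg0)$trimmed)
})

test_that("adapter localization matches the exhaustive (position x edit) oracle", {
  adapter <- "TGGAATTCTCGGG"
  set.seed(42)
  cases <- list()
  for (i in 1:25) {
    ins <- paste(sample(c("A", "C", "G", "T"), sample(10:25, 1), TRUE),
                 collapse = "")
    kind <- i %% 5
    seq <- if (kind == 0) ins                                # no adapter
    else if (kind == 1) paste0(ins, adapter)                 # exact
    else if (kind == 2) {                                    # 1 substitution
      m <- adapter; p <- sample(nchar(adapter), 1)
      substring(m, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substring(m, p, p))[1]
      paste0(ins, m)
    } else if (kind == 3)                                    # 1 deletion
      paste0(ins, sub("^(.{5}).", "\\1", adapter))
    else paste0(ins, substring(adapter, 1, 11))              # overhang
    cases[[i]] <- seq
  }
  for (md in 0:2) {
    cfg <- preprocess_config(adapter3 = adapter, max_adapter_edit_dist = md,
                             min_overlap = 6)
    got <- adapter_scan(unlist(cases), cfg)
    want <- vapply(cases, oracle_adapter_trim, 0L, adapter = adapter,
                   max_dist = md, min_overlap = 6)
    expect_equal(got, unname(want), info = paste("max_dist", md))
  }
})

test_that("adapter trimming is idempotent", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  cfg <- preprocess_config(adapter3 = adapter)
  set.seed(9)
  for (i in 1:10) {
    ins <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
    r <- list(sequence = paste0(ins, adapter), quality = rep(40L, 43))
    once <- trim_adapter(r, cfg)
    twice <- trim_adapter(once, cfg)
    expect_equal(twice$sequence, once$sequence)
  }
})

test_that("sliding-window quality trimming truncates at the first failing window", {
  cfg <- preprocess_config(qual_window = 4, qual_threshold = 20)
  # all high: unchanged
  r <- list(sequence = "ACGTACGT", quality = rep(40L, 8))
  expect_equal(quality_trim(r, cfg)$sequence, "ACGTACGT")
  # hand-enumerated 7-mer: windows [1]30.5 [2]21 [3]11.5 [4]2 -> cut at 3
  r <- list(sequence = "ACGTACG", quality = c(40, 40, 40, 2, 2, 2, 2))
  qt <- quality_trim(r, cfg)
  expect_equal(qt$sequence, "AC")
  expect_length(qt$quality, 2)
  # fully bad read trims to length 0
  r <- list(sequence = "ACGT", quality = rep(2L, 4))
  expect_equal(nchar(quality_trim(r, cfg)$sequence), 0)
})

test_that("fixed-base extraction removes barcodes and reads the UMI", {
  cfg0 <- preprocess_config()
  r <- list(sequence = "ACGTACGTACGTACGTAC", quality = rep(40L, 18))
  ex <- extract_fixed_bases(r, cfg0)
  expect_equal(ex$sequence, r$sequence)
  expect_equal(ex$umi, "")

  cfg <- preprocess_config(umi_len = 4, umi_side = "five_prime")
  r <- list(sequence = "NNNNACGTACGTACGTACGTAC", quality = rep(40L, 22))
  ex <- extract_fixed_bases(r, cfg)
  expect_equal(ex$umi, "NNNN")
  expect_equal(ex$sequence, "ACGTACGTACGTACGTAC")

  cfg <- preprocess_config(barcode5_len = 2, umi_len = 4)
  r <- list(sequence = "ACGTACGTACGTACGTAC", quality = rep(40L, 18))
  ex <- extract_fixed_bases(r, cfg)
  expect_equal(nchar(ex$sequence), 12)
  expect_length(ex$quality, 12)

  # shorter than the fixed bases: dropped
  cfg <- preprocess_config(barcode5_len = 10, umi_len = 10)
  expect_null(extract_fixed_bases(list(sequence = "ACGTACGT",
                                       quality = rep(40L, 8)), cfg))
})

test_that("read collapsing counts multiplicities and distinct UMIs", {
  expect_equal(collapse_reads("A")$count, 1L)
  cc <- collapse_reads(c(rep("ACGT", 3), "GGGG"))
  expect_equal(setNames(cc$count, cc$sequence), c(ACGT = 3L, GGGG = 1L))
  # distinct-UMI counting
  cc <- collapse_reads(rep("ACGT", 3), c("AAAA", "AAAA", "CCCC"))
  expect_equal(cc$count, 2L)
  # conservation without UMIs
  set.seed(3)
  seqs <- sample(c("AA", "CC", "GG", "TT"), 200, TRUE)
  expect_equal(sum(collapse_reads(seqs)$count), 200L)
})

test_that("QC statistics report GC content and conserve read counts", {
  mk <- function(seqs) list(id = seq_along(seqs), sequence = seqs,
                            quality = lapply(nchar(seqs), function(L) rep(40L, L)))
  expect_equal(compute_qc(NULL, mk("GCGC"))$gc_percent, 100)
  expect_equal(compute_qc(NULL, mk("ACGT"))$gc_percent, 50)
  expect_equal(compute_qc(NULL, mk(c("AAAA", "GGGG")))$gc_percent, 50)
  q <- compute_qc(mk(c("AA", "CC", "GG")), mk(c("AA", "CC")),
                  c(too_short = 1L))
  expect_equal(q$n_raw, 3L)
  expect_equal(q$n_kept + sum(q$n_dropped), q$n_raw)
  expect_equal(sum(q$length_histogram), q$n_kept)
  # zero kept reads: gc undefined
  expect_true(is.na(compute_qc(mk("AC"), mk(character()))$gc_percent))
})

test_that("per-sample preprocessing conserves reads across drop reasons", {
  spec <- simulation_spec(seed = 21, n_samples = 1, n_mirnas = 8,
                          depth_per_sample = 800)
  study <- simulate_study(spec, genome_len = 20000)
  res <- preprocess_sample(study$samples$sample01,
                           preprocess_config(adapter3 = spec$adapter))
  q <- res$qc
  expect_equal(q$n_kept + sum(q$n_dropped), q$n_raw)
  expect_equal(sum(res$collapsed$count), q$n_kept)
})

test_that("collapsed-read compression is lossless and round-trips", {
  col <- collapse_reads(c(rep("ACGTACGTAC", 5), rep("GGGGCCCCAA", 2), "TTTT"))
  enc <- compress_collapsed(col, raw_fastq_bytes = 1000)
  dec <- decompress_collapsed(enc$payload)
  expect_equal(dec, col)
  # empty sample: ratio 0, empty payload
  e <- compress_collapsed(collapse_reads(character()), 0)
  expect_equal(e$ratio, 0)
  expect_length(e$payload, 0)
})

test_that("FASTQ and collapsed-FASTA I/O round-trip", {
  reads <- list(id = c("r1", "r2"), sequence = c("ACGTACGTACGT", "GGGGCCCC"),
                quality = list(rep(38L, 12), c(40L, 40L, 30L, 30L, 20L, 20L, 10L, 10L)))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)

  col <- collapse_reads(c(rep("ACGTACGTAC", 4), "GGGGCCCCAA"))
  fa <- tempfile(fileext = ".fa")
  write_collapsed_fasta(col, fa)
  expect_equal(read_collapsed_fasta(fa), col)
})
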