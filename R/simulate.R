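## Synthetic-data generator: toy genomes with planted hairpin precursors,
## multi-sample FASTQ simulation with adapters/UMIs/errors, planted
## differential expression and batch effects, and matching ground truth.
## Fully deterministic under a fixed seed.

#' Simulation specification
#'
#' Defines the study conditions of a simulated small-RNA experiment.
#'
#' @param seed integer RNG seed; every downstream draw derives from it.
#' @param n_samples number of samples.
#' @param groups named character vector `sample -> level`; defaults to two
#'   equal groups A/B.
#' @param batch named character vector `sample -> batch`; defaults to two
#'   alternating batches.
#' @param n_mirnas number of annotated (known) miRNA hairpins planted in the
#'   genome.
#' @param n_novel number of unannotated hairpins (discovery targets).
#' @param n_other named integer vector of feature counts for additional
#'   ncRNA classes.
#' @param depth_per_sample reads emitted per sample (exactly).
#' @param zipf_exponent abundance skew of the Zipf model (default 1.2, the
#'   typical skew of small-RNA libraries).
#' @param planted_fc named numeric vector `feature -> log2 fold change`
#'   applied multiplicatively to the second group level.
#' @param batch_shift_sd sd (log2 scale) of per-(feature, batch) lognormal
#'   abundance factors; 0 disables batch effects.
#' @param error_rate per-base substitution probability.
#' @param adapter 3' adapter appended to every read (may be `NULL`).
#' @param umi_len length of the random UMI prepended to each read.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1L, n_samples = 4L, groups = NULL,
                            batch = NULL, n_mirnas = 20L, n_novel = 0L,
                            n_other = c(tRNA = 5L, rRNA = 3L, snoRNA = 4L),
                            depth_per_sample = 10000L, zipf_exponent = 1.2,
                            planted_fc = numeric(), batch_shift_sd = 0,
                            error_rate = 0.001,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            umi_len = 0L) {
  samples <- sprintf("sample%02d", seq_len(n_samples))
  if (is.null(groups))
    groups <- setNames(rep(c("A", "B"), length.out = n_samples), samples)
  if (is.null(batch))
    batch <- setNames(rep(c("b1", "b2"), each = ceiling(n_samples / 2))[
      seq_len(n_samples)], samples)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 samples = samples, groups = groups, batch = batch,
                 n_mirnas = as.integer(n_mirnas), n_novel = as.integer(n_novel),
                 n_other = n_other,
                 depth_per_sample = as.integer(depth_per_sample),
                 zipf_exponent = zipf_exponent, planted_fc = planted_fc,
                 batch_shift_sd = batch_shift_sd, error_rate = error_rate,
                 adapter = adapter, umi_len = as.integer(umi_len)),
            class = "simulation_spec")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Build a toy reference bundle with planted hairpins
#'
#' Generates a single-contig genome containing `n_mirnas` annotated hairpin
#' precursors (perfectly complementary 22-nt arms around an 8-nt loop) and
#' `n_novel` unannotated hairpins, plus sequence-space references for the
#' other requested ncRNA classes. Writes nothing; use [write_bundle()] to
#' export. Deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @param genome_len genome length in nt (default 50000).
#' @return list with `bundle` (a `reference_bundle`) and `truth`
#'   (planted precursor/mature coordinates and novel loci).
#' @export
make_toy_bundle <- function(spec, genome_len = 50000L) {
  set.seed(spec$seed)
  arm <- 22L; loop <- 8L; flank <- 5L
  hp_len <- 2L * arm + loop
  n_hp <- spec$n_mirnas + spec$n_novel
  genome <- strsplit(random_dna(genome_len), "")[[1]]
  slot_w <- genome_len %/% max(1L, n_hp + 1L)
  stopifnot(slot_w > hp_len + 2L * flank)
  truth_rows <- list()
  precursors <- character(); matures <- list()
  for (i in seq_len(n_hp)) {
    arm5 <- random_dna(arm)
    arm3 <- revcomp(arm5)
    hp <- paste0(arm5, random_dna(loop), arm3)
    gstart <- (i - 1L) * slot_w + (slot_w - hp_len) %/% 2L   # 0-based
    genome[(gstart + 1L):(gstart + hp_len)] <- strsplit(hp, "")[[1]]
    known <- i <= spec$n_mirnas
    pid <- if (known) sprintf("mir-%03d", i) else sprintf("novel-%03d", i)
    truth_rows[[i]] <- data.frame(
      precursor_id = pid, known = known,
      g_start = gstart, g_end = gstart + hp_len,
      arm5_start = gstart, arm5_end = gstart + arm,
      arm3_start = gstart + arm + loop, arm3_end = gstart + hp_len,
      stringsAsFactors = FALSE)
    if (known) {
      pre_seq <- paste0(
        paste(genome[max(1L, gstart + 1L - flank):gstart], collapse = ""),
        hp,
        paste(genome[(gstart + hp_len + 1L):(gstart + hp_len + flank)],
              collapse = ""))
      precursors[pid] <- pre_seq
      matures[[length(matures) + 1L]] <- data.frame(
        precursor_id = pid,
        mature_id = paste0(pid, c("-5p", "-3p")),
        start = c(flank, flank + arm + loop),
        end = c(flank + arm, flank + hp_len),
        arm = c("5p", "3p"), stringsAsFactors = FALSE)
    }
  }
  matures <- do.call(rbind, matures)
  truth <- do.call(rbind, truth_rows)

  ncrna <- list()
  for (cls in names(spec$n_other)) {
    k <- spec$n_other[[cls]]
    if (k > 0L)
      ncrna[[cls]] <- setNames(
        vapply(seq_len(k), function(j) random_dna(sample(60:90, 1L)), ""),
        sprintf("%s-%03d", cls, seq_len(k)))
  }
  # class features live in the genome too (after the hairpin slots) so that
  # class-derived reads contribute to genome-mapped depth
  tail_seqs <- unlist(lapply(ncrna, function(s)
    paste0(vapply(seq_along(s), function(j) random_dna(20L), ""), s)))
  genome_seq <- c(chr1 = paste0(paste(genome, collapse = ""),
                                paste(tail_seqs, collapse = "")))

  known_seqs <- character()
  for (i in seq_len(nrow(matures)))
    known_seqs <- c(known_seqs,
                    substring(precursors[[matures$precursor_id[i]]],
                              matures$start[i] + 1L, matures$end[i]))

  kt <- truth[truth$known, , drop = FALSE]
  mirna_genomic <- NULL
  if (nrow(kt) > 0L) {
    gr_pre <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(kt$g_start + 1L - flank, kt$g_end + flank))
    gr_pre$type <- "miRNA_primary_transcript"; gr_pre$Name <- kt$precursor_id
    gr_m5 <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(kt$arm5_start + 1L, kt$arm5_end))
    gr_m5$type <- "miRNA"; gr_m5$Name <- paste0(kt$precursor_id, "-5p")
    gr_m3 <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(kt$arm3_start + 1L, kt$arm3_end))
    gr_m3$type <- "miRNA"; gr_m3$Name <- paste0(kt$precursor_id, "-3p")
    mirna_genomic <- c(gr_pre, gr_m5, gr_m3)
  }

  bundle <- structure(list(genome = genome_seq, precursors = precursors,
                           matures = matures, ncrna_classes = ncrna,
                           known_mature_seqs = unique(known_seqs),
                           mirna_genomic = mirna_genomic),
                      class = "reference_bundle")
  list(bundle = bundle, truth = truth)
}

## Zipf(s) probabilities over n ranks.
zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

#' Simulate one sample's reads
#'
#' Reads are drawn from the mature miRNA and ncRNA-class feature sequences
#' under a Zipf abundance model; group effects multiply abundances by
#' `2^planted_fc` in the second level, batch shifts act as per-(feature,
#' batch) lognormal factors, substitution errors are applied per base, the
#' 3' adapter is appended and a random UMI prepended. Qualities are high
#' (Phred 36-40) with a mildly degraded 3' tail. Exactly
#' `spec$depth_per_sample` reads are emitted.
#'
#' @param bundle a `reference_bundle` from [make_toy_bundle()].
#' @param spec a [simulation_spec()].
#' @param sample sample id (must appear in `spec$samples`).
#' @param truth optional planted-locus table from [make_toy_bundle()]; when
#'   given, the arms of unannotated (novel) hairpins also produce reads so
#'   the discovery module has signal.
#' @return list with `reads` (a raw-read set as in [read_fastq()]) and
#'   `truth_counts` (named true read counts per feature).
#' @export
simulate_sample_reads <- function(bundle, spec, sample, truth = NULL) {
  si <- match(sample, spec$samples)
  stopifnot(!is.na(si))
  feat_seqs <- c(setNames(
    substring(bundle$precursors[bundle$matures$precursor_id],
              bundle$matures$start + 1L, bundle$matures$end),
    bundle$matures$mature_id),
    unlist(unname(lapply(bundle$ncrna_classes, identity))))
  if (!is.null(truth) && any(!truth$known)) {
    nv <- truth[!truth$known, , drop = FALSE]
    g <- bundle$genome[[1]]
    novel_seqs <- c(setNames(substring(g, nv$arm5_start + 1L, nv$arm5_end),
                             paste0(nv$precursor_id, "-5p")),
                    setNames(substring(g, nv$arm3_start + 1L, nv$arm3_end),
                             paste0(nv$precursor_id, "-3p")))
    feat_seqs <- c(feat_seqs, novel_seqs)
  }
  nf <- length(feat_seqs)
  set.seed(spec$seed + 1000L)
  base_p <- zipf_probs(nf, spec$zipf_exponent)[sample.int(nf)]
  batch_ids <- sort(unique(unname(spec$batch)))
  shift <- matrix(0, nf, length(batch_ids),
                  dimnames = list(names(feat_seqs), batch_ids))
  if (spec$batch_shift_sd > 0)
    shift[] <- rnorm(nf * length(batch_ids), 0, spec$batch_shift_sd)
  p <- base_p
  lvl <- spec$groups[[sample]]
  if (length(spec$planted_fc) && lvl == sort(unique(unname(spec$groups)))[2]) {
    idx <- match(names(spec$planted_fc), names(feat_seqs))
    ok <- !is.na(idx)
    p[idx[ok]] <- p[idx[ok]] * 2^spec$planted_fc[ok]
  }
  p <- p * 2^shift[, spec$batch[[sample]]]
  p <- p / sum(p)
  set.seed(spec$seed + 17L * si)
  counts <- as.integer(stats::rmultinom(1L, spec$depth_per_sample, p))
  names(counts) <- names(feat_seqs)
  seqs <- rep(unname(feat_seqs), counts)
  # per-base substitution errors
  if (spec$error_rate > 0 && length(seqs)) {
    lens <- nchar(seqs)
    nerr <- rbinom(length(seqs), lens, spec$error_rate)
    for (r in which(nerr > 0L)) {
      ch <- strsplit(seqs[r], "")[[1]]
      at <- sample.int(length(ch), nerr[r])
      ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(DNA_BASES, b), 1L), "")
      seqs[r] <- paste(ch, collapse = "")
    }
  }
  if (spec$umi_len > 0L && length(seqs)) {
    umis <- vapply(seq_along(seqs), function(i) random_dna(spec$umi_len), "")
    seqs <- paste0(umis, seqs)
  }
  if (!is.null(spec$adapter)) seqs <- paste0(seqs, spec$adapter)
  lens <- nchar(seqs)
  qual <- lapply(lens, function(L) {
    q <- rep.int(40L, L)
    tail_n <- min(5L, L)
    q[(L - tail_n + 1L):L] <- 36L
    q
  })
  ord <- sample.int(length(seqs))   # shuffle read order
  list(reads = list(id = sprintf("%s_r%06d", sample, seq_along(seqs)),
                    sequence = seqs[ord], quality = qual[ord]),
       truth_counts = counts)
}

#' Simulate a complete multi-sample study
#'
#' @param spec a [simulation_spec()].
#' @param genome_len genome length passed to [make_toy_bundle()].
#' @return list with `bundle`, `truth` (planted loci), `samples` (named list
#'   of raw-read sets), `truth_counts` (features x samples matrix),
#'   `annotation` (data.frame sample/group/batch).
#' @export
simulate_study <- function(spec, genome_len = 50000L) {
  tb <- make_toy_bundle(spec, genome_len)
  samples <- list(); tc <- list()
  for (s in spec$samples) {
    sim <- simulate_sample_reads(tb$bundle, spec, s, tb$truth)
    samples[[s]] <- sim$reads
    tc[[s]] <- sim$truth_counts
  }
  list(bundle = tb$bundle, truth = tb$truth, samples = samples,
       truth_counts = do.call(cbind, tc),
       annotation = data.frame(sample = spec$samples,
                               group = unname(spec$groups[spec$samples]),
                               batch = unname(spec$batch[spec$samples]),
                               stringsAsFactors = FALSE))
}

#' Simulate a low-complexity FASTQ sample
#'
#' Emulates the duplicate-heavy structure of miRNA-seq libraries: `n_reads`
#' reads drawn from `n_seqs` distinct sequences under a Zipf abundance model,
#' with uniform high qualities. Used to exercise read collapsing and
#' compression.
#'
#' @param n_reads total reads.
#' @param n_seqs distinct sequence count.
#' @param read_len read length in nt.
#' @param zipf_exponent Zipf skew (default 1.5).
#' @param seed RNG seed.
#' @param path optional output path; when given the FASTQ is written there.
#' @return list with `sequences` (per-read), `raw_bytes` (byte size of the
#'   FASTQ representation) and `path` (or `NULL`).
#' @export
simulate_low_complexity_fastq <- function(n_reads = 1e6L, n_seqs = 500L,
                                          read_len = 22L, zipf_exponent = 1.5,
                                          seed = 1L, path = NULL) {
  set.seed(seed)
  pool <- vapply(seq_len(n_seqs), function(i) random_dna(read_len), "")
  idx <- sample.int(n_seqs, n_reads, replace = TRUE,
                    prob = zipf_probs(n_seqs, zipf_exponent))
  seqs <- pool[idx]
  ids <- sprintf("@r%d", seq_len(n_reads))
  qual <- strrep("I", read_len)
  # bytes of the 4-line records including newlines
  raw_bytes <- sum(nchar(ids)) + n_reads * (read_len + 1L + 1L + 1L +
                                              read_len + 1L + 1L)
  if (!is.null(path)) {
    con <- file(path, "wb")
    writeLines(paste0(ids, "\n", seqs, "\n+\n", qual), con)
    close(con)
    raw_bytes <- file.size(path)
  }
  list(sequences = seqs, raw_bytes = raw_bytes, path = path)
}

#' Simulate a normalized expression matrix with planted effects
#'
#' Direct matrix-level generator for statistical calibration: features x
#' samples log2-scale values `baseline + group effect + batch shift +
#' N(0, sigma)`. Used for type-I error, DE power/FDR and PVCA recovery
#' checks without running the read-level pipeline.
#'
#' @param n_features,n_samples matrix dimensions.
#' @param groups named character vector `sample -> level` (default two
#'   halves A/B).
#' @param batch optional named character vector `sample -> batch`.
#' @param de_features indices of features given the group effect.
#' @param log2fc group effect size (added to level 2 samples).
#' @param batch_shift additive shift (in sd units times `sigma`) applied to
#'   all features of the second batch.
#' @param sigma residual noise sd.
#' @param baseline_mean mean baseline log2 expression.
#' @param seed RNG seed.
#' @return list with `values` (log2 matrix), `rpm` (back-transformed),
#'   `groups`, `batch`, `de_features`.
#' @export
simulate_expression_matrix <- function(n_features = 2000L, n_samples = 40L,
                                       groups = NULL, batch = NULL,
                                       de_features = integer(), log2fc = 0,
                                       batch_shift = 0, sigma = 1,
                                       baseline_mean = 6, seed = 1L) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n_samples))
  if (is.null(groups))
    groups <- setNames(rep(c("A", "B"), each = ceiling(n_samples / 2))[
      seq_len(n_samples)], samples)
  baseline <- runif(n_features, baseline_mean - 2, baseline_mean + 2)
  values <- matrix(rnorm(n_features * n_samples, 0, sigma),
                   n_features, n_samples,
                   dimnames = list(sprintf("f%04d", seq_len(n_features)),
                                   samples)) + baseline
  lvl2 <- sort(unique(unname(groups)))[2]
  if (length(de_features) && log2fc != 0)
    values[de_features, groups[samples] == lvl2] <-
      values[de_features, groups[samples] == lvl2] + log2fc
  if (!is.null(batch) && batch_shift != 0) {
    b2 <- sort(unique(unname(batch)))[2]
    values[, batch[samples] == b2] <-
      values[, batch[samples] == b2] + batch_shift * sigma
  }
  values <- pmax(values, 0)
  list(values = values, rpm = 2^values - 1, groups = groups, batch = batch,
       de_features = de_features)
}
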