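## FASTQ preprocessing: adapter trimming, fixed-base (barcode/UMI) extraction,
## sliding-window quality trimming, N handling, read collapsing and
## compression, plus per-sample QC statistics.

#' Preprocessing configuration
#'
#' Bundles every knob of the read preprocessing stage. Defaults follow
#' community-conventional small-RNA settings and can all be overridden.
#'
#' @param adapter3 3' adapter sequence, or `NULL` to skip adapter trimming.
#' @param barcode5_len number of fixed bases removed from the 5' end.
#' @param adapter_barcode_len number of fixed bases removed from the 3' end
#'   (the bases adjacent to the adapter after trimming).
#' @param umi_len UMI length in nt; 0 disables UMI handling.
#' @param umi_side side of the insert the UMI is read from
#'   (`"five_prime"` or `"three_prime"`).
#' @param min_read_len minimum insert length kept after all trimming.
#' @param max_adapter_edit_dist maximum edit distance (substitutions and
#'   indels) tolerated for an adapter occurrence.
#' @param min_overlap minimum number of read bases an adapter occurrence must
#'   cover.
#' @param qual_window sliding-window width for quality trimming.
#' @param qual_threshold minimum mean Phred quality of a window.
#' @param n_policy `"trim_ends"` strips leading/trailing N, `"drop_read"`
#'   discards any read containing N, `"keep"` leaves N untouched.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(adapter3 = NULL,
                              barcode5_len = 0L,
                              adapter_barcode_len = 0L,
                              umi_len = 0L,
                              umi_side = c("five_prime", "three_prime"),
                              min_read_len = 18L,
                              max_adapter_edit_dist = 1L,
                              min_overlap = 10L,
                              qual_window = 4L,
                              qual_threshold = 20L,
                              n_policy = c("trim_ends", "drop_read", "keep")) {
  umi_side <- match.arg(umi_side)
  n_policy <- match.arg(n_policy)
  stopifnot(min_read_len >= 1L, max_adapter_edit_dist >= 0L, min_overlap >= 1L,
            qual_window >= 1L, barcode5_len >= 0L, umi_len >= 0L,
            adapter_barcode_len >= 0L)
  if (!is.null(adapter3) && max_adapter_edit_dist >= nchar(adapter3))
    stop("max_adapter_edit_dist must be smaller than the adapter length")
  structure(list(adapter3 = adapter3, barcode5_len = as.integer(barcode5_len),
                 adapter_barcode_len = as.integer(adapter_barcode_len),
                 umi_len = as.integer(umi_len), umi_side = umi_side,
                 min_read_len = as.integer(min_read_len),
                 max_adapter_edit_dist = as.integer(max_adapter_edit_dist),
                 min_overlap = as.integer(min_overlap),
                 qual_window = as.integer(qual_window),
                 qual_threshold = as.integer(qual_threshold),
                 n_policy = n_policy),
            class = "preprocess_config")
}

#' Read a FASTQ file into a raw-read set
#'
#' Reads plain or gzip-compressed FASTQ (Phred+33) via Biostrings.
#'
#' @param path FASTQ or FASTQ.gz file.
#' @return a list with `id`, `sequence` (character) and `quality`
#'   (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  # Biostrings emits a benign "metadata columns dropped" warning while
  # assembling/converting the quality-scaled set
  qs <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  qual <- suppressWarnings(as(Biostrings::quality(qs), "IntegerList"))
  list(id = names(qs) %||% paste0("read", seq_along(qs)),
       sequence = suppressWarnings(unname(as.character(qs))),
       quality = as.list(qual))
}

#' Write reads to a FASTQ file
#'
#' @param reads a raw-read set as returned by [read_fastq()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  qchar <- vapply(reads$quality, function(q) intToUtf8(q + 33L), "")
  rec <- paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qchar)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

## Semi-global edit distance of `adapter` anchored at the start of `suffix`:
## free end gaps in both dimensions (adapter may be internal -- remaining read
## bases are discarded anyway -- or may overhang the read 3' end). Returns the
## minimum distance over alignments covering >= min_cover read bases.
adapter_suffix_dist <- function(adapter_chars, suffix_chars, min_cover,
                                max_d = Inf) {
  la <- length(adapter_chars)
  m <- length(suffix_chars)
  if (m < min_cover) return(Inf)
  prev <- c(0L, rep.int(1000000L, m))   # D[0, ]: adapter must start at p
  best <- Inf
  for (i in seq_len(la)) {
    cur <- integer(m + 1L)
    cur[1L] <- i                         # D[i,0] = i deletions
    sub <- prev[1:m] + (adapter_chars[i] != suffix_chars)
    # row-wise min with left-to-right dependency (insertion in read)
    del <- prev[2:(m + 1L)] + 1L
    v <- pmin(sub, del)
    for (j in seq_len(m)) {
      x <- min(v[j], cur[j] + 1L)
      cur[j + 1L] <- x
    }
    prev <- cur
    # overhang: read consumed, adapter tail free
    best <- min(best, prev[m + 1L])
    if (i == la) best <- min(best, min(prev[(min_cover + 1L):(m + 1L)]))
    # row minima of the edit DP are non-decreasing in i: prune hopeless rows
    if (min(prev) > max_d && best > max_d) return(Inf)
  }
  best
}

#' Trim a 3' adapter from reads
#'
#' Scans every candidate start position for the best adapter occurrence by
#' semi-global alignment (substitutions and indels each cost 1), keeping the
#' occurrence with minimal edit distance; ties go to the leftmost position so
#' the longest possible adapter stretch is removed. Occurrences must cover at
#' least `cfg$min_overlap` read bases and have distance at most
#' `cfg$max_adapter_edit_dist`.
#'
#' @param sequences character vector of read sequences.
#' @param cfg a [preprocess_config()].
#' @return integer vector of insert lengths: number of 5' bases kept per read,
#'   `NA` where no qualifying occurrence exists (read left unchanged).
#' @export
adapter_scan <- function(sequences, cfg) {
  if (is.null(cfg$adapter3)) return(rep(NA_integer_, length(sequences)))
  adapter <- cfg$adapter3
  la <- nchar(adapter)
  ach <- strsplit(adapter, "")[[1]]
  max_d <- cfg$max_adapter_edit_dist
  min_ov <- cfg$min_overlap
  out <- rep(NA_integer_, length(sequences))

  ## fast path: exact internal occurrence or exact overhanging prefix
  exact_pos <- as.integer(regexpr(adapter, sequences, fixed = TRUE))
  for (r in seq_along(sequences)) {
    s <- sequences[r]
    n <- nchar(s)
    pmax_ <- n - min_ov + 1L
    if (pmax_ < 1L) next
    best_d <- Inf; best_p <- NA_integer_
    ep <- exact_pos[r]
    if (ep > 0L && ep <= pmax_ && la >= min_ov) { best_d <- 0; best_p <- ep }
    if (is.finite(best_d) || max_d == 0L) {
      # still check exact overhangs left of ep (shorter coverage, earlier p)
      lim <- if (is.finite(best_d)) best_p - 1L else pmax_
      p <- max(n - la + 2L, 1L)
      while (p <= lim) {
        if (substring(s, p, n) == substring(adapter, 1L, n - p + 1L)) {
          best_d <- 0; best_p <- p; break
        }
        p <- p + 1L
      }
      if (is.finite(best_d)) { out[r] <- best_p - 1L; next }
      if (max_d == 0L) next
    }
    sch <- strsplit(s, "")[[1]]
    for (p in seq_len(pmax_)) {
      d <- adapter_suffix_dist(ach, sch[p:n], min_ov, max_d)
      if (d <= max_d && d < best_d) { best_d <- d; best_p <- p
        if (d == 0) break }
    }
    if (is.finite(best_d)) out[r] <- best_p - 1L
  }
  out
}

#' Trim the adapter from a single read
#'
#' @param read list with `sequence` and `quality` (integer Phred vector).
#' @param cfg a [preprocess_config()].
#' @return the read with sequence and quality truncated before the adapter,
#'   plus a logical `trimmed` element.
#' @export
trim_adapter <- function(read, cfg) {
  keep <- adapter_scan(read$sequence, cfg)
  if (is.na(keep)) {
    read$trimmed <- FALSE
  } else {
    read$sequence <- substring(read$sequence, 1L, keep)
    read$quality <- read$quality[seq_len(keep)]
    read$trimmed <- TRUE
  }
  read
}

#' Quality-trim the 3' end of a read
#'
#' Windows of width `cfg$qual_window` slide 5' to 3' in steps of one base;
#' the read is truncated at the first base of the first window whose mean
#' Phred quality falls below `cfg$qual_threshold`. Reads shorter than the
#' window are assessed as a single whole-read window.
#'
#' @inheritParams trim_adapter
#' @return the read, possibly truncated (length 0 allowed).
#' @export
quality_trim <- function(read, cfg) {
  q <- read$quality
  L <- length(q)
  if (L == 0L) return(read)
  w <- min(cfg$qual_window, L)
  cs <- cumsum(c(0L, q))
  means <- (cs[(w + 1L):(L + 1L)] - cs[1:(L - w + 1L)]) / w
  bad <- which(means < cfg$qual_threshold)
  if (length(bad)) {
    cut <- bad[1L] - 1L
    read$sequence <- substring(read$sequence, 1L, cut)
    read$quality <- q[seq_len(cut)]
  }
  read
}

#' Extract fixed bases (5' barcode, adapter barcode, UMI) from a read
#'
#' Removes `barcode5_len` bases from the 5' end and `adapter_barcode_len`
#' bases from the 3' end (the bases that sat next to the adapter), then reads
#' `umi_len` bases off the configured side as the UMI.
#'
#' @inheritParams trim_adapter
#' @return the read with insert sequence/quality and a `umi` element, or
#'   `NULL` when the read is shorter than the fixed bases (dropped).
#' @export
extract_fixed_bases <- function(read, cfg) {
  n <- nchar(read$sequence)
  fixed5 <- cfg$barcode5_len + if (cfg$umi_side == "five_prime") cfg$umi_len else 0L
  fixed3 <- cfg$adapter_barcode_len + if (cfg$umi_side == "three_prime") cfg$umi_len else 0L
  if (n < fixed5 + fixed3) return(NULL)
  umi <- ""
  if (cfg$umi_len > 0L) {
    umi <- if (cfg$umi_side == "five_prime")
      substring(read$sequence, cfg$barcode5_len + 1L, cfg$barcode5_len + cfg$umi_len)
    else
      substring(read$sequence, n - cfg$adapter_barcode_len - cfg$umi_len + 1L,
                n - cfg$adapter_barcode_len)
  }
  read$sequence <- substring(read$sequence, fixed5 + 1L, n - fixed3)
  read$quality <- read$quality[(fixed5 + 1L):(n - fixed3)][seq_len(n - fixed5 - fixed3)]
  read$umi <- umi
  read
}

#' Collapse reads to unique sequences
#'
#' Without UMIs each record's count is the sequence multiplicity; with UMIs
#' it is the number of distinct UMIs seen for that sequence (exact-match
#' deduplication, no error-correction clustering).
#'
#' @param sequences character vector of trimmed read sequences.
#' @param umis character vector of UMIs (same length), or `NULL`/all-empty
#'   for plain collapsing.
#' @return data.frame with `sequence` and `count`, ordered by decreasing
#'   count then sequence.
#' @export
collapse_reads <- function(sequences, umis = NULL) {
  if (length(sequences) == 0L)
    return(data.frame(sequence = character(), count = integer()))
  use_umi <- !is.null(umis) && any(nzchar(umis))
  dt <- data.table::data.table(sequence = sequences)
  if (use_umi) {
    dt$umi <- umis
    res <- dt[, list(count = length(unique(umi))), by = "sequence"]
  } else {
    res <- dt[, list(count = .N), by = "sequence"]
  }
  res <- res[order(-count, sequence)]
  out <- as.data.frame(res)
  out$count <- as.integer(out$count)
  out
}

#' Per-sample QC statistics
#'
#' @param raw raw-read set before filtering (may be `NULL` to reuse kept).
#' @param kept raw-read set after preprocessing.
#' @param n_dropped named integer vector of per-reason drop counts.
#' @return list with `n_raw`, `n_kept`, `length_histogram`, `gc_percent`
#'   (GC over A/C/G/T bases of kept reads; `NA` when nothing is kept),
#'   `mean_quality_by_position` and `n_dropped`.
#' @export
compute_qc <- function(raw, kept, n_dropped = integer()) {
  n_raw <- length(raw$sequence %||% kept$sequence)
  n_kept <- length(kept$sequence)
  lens <- nchar(kept$sequence)
  hist <- table(factor(lens, levels = if (n_kept) seq_len(max(lens)) else integer()))
  gc <- NA_real_
  if (n_kept > 0L) {
    freq <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(kept$sequence))[, DNA_BASES, drop = FALSE])
    denom <- sum(freq)
    if (denom > 0) gc <- 100 * (freq[["G"]] + freq[["C"]]) / denom
  }
  mq <- numeric()
  if (n_kept > 0L) {
    maxlen <- max(lens)
    sums <- numeric(maxlen); cnt <- numeric(maxlen)
    for (q in kept$quality) {
      L <- length(q)
      if (L) { sums[1:L] <- sums[1:L] + q; cnt[1:L] <- cnt[1:L] + 1 }
    }
    mq <- ifelse(cnt > 0, sums / cnt, NA_real_)
  }
  list(n_raw = n_raw, n_kept = n_kept,
       length_histogram = hist, gc_percent = unname(gc),
       mean_quality_by_position = mq, n_dropped = n_dropped)
}

#' Serialize and compress a collapsed read set
#'
#' Collapsed reads are written as `sequence<TAB>count` lines and
#' gzip-compressed. The reported ratio is the size reduction relative to the
#' originating raw FASTQ bytes.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param raw_fastq_bytes byte size of the raw FASTQ the reads came from.
#' @return list with `payload` (raw vector) and `ratio`
#'   (`1 - compressed/raw`, 0 for an empty sample).
#' @export
compress_collapsed <- function(collapsed, raw_fastq_bytes) {
  if (nrow(collapsed) == 0L)
    return(list(payload = raw(), ratio = 0))
  txt <- paste0(collapsed$sequence, "\t", collapsed$count, "\n", collapse = "")
  payload <- gzip_bytes(txt)
  ratio <- if (raw_fastq_bytes > 0) 1 - length(payload) / raw_fastq_bytes else 0
  list(payload = payload, ratio = ratio)
}

#' Decode a compressed collapsed read set
#'
#' Inverse of [compress_collapsed()]; the round trip is lossless for
#' (sequence, count) content.
#'
#' @param payload raw vector from [compress_collapsed()].
#' @return data.frame with `sequence` and `count`.
#' @export
decompress_collapsed <- function(payload) {
  if (length(payload) == 0L)
    return(data.frame(sequence = character(), count = integer()))
  lines <- strsplit(gunzip_text(payload), "\n", fixed = TRUE)[[1]]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(sequence = vapply(parts, `[`, "", 1L),
             count = as.integer(vapply(parts, `[`, "", 2L)))
}

apply_n_policy <- function(seq, qual, policy) {
  if (policy == "keep") return(list(sequence = seq, quality = qual))
  if (policy == "drop_read") {
    if (grepl("N", seq, fixed = TRUE)) return(NULL)
    return(list(sequence = seq, quality = qual))
  }
  # trim_ends: strip leading/trailing N runs; internal N kept
  m <- regmatches(seq, regexec("^(N*)(.*?)(N*)$", seq))[[1]]
  lead <- nchar(m[2]); core <- m[3]
  list(sequence = core, quality = qual[lead + seq_len(nchar(core))])
}

#' Preprocess one sample
#'
#' Runs the full per-read pipeline: adapter trimming, fixed-base/UMI
#' extraction, sliding-window quality trimming, N policy, minimum-length
#' filtering, then read collapsing, QC and compression. Adapter trimming is
#' applied before quality trimming.
#'
#' @param reads raw-read set from [read_fastq()], or a path to a FASTQ file.
#' @param cfg a [preprocess_config()].
#' @param raw_fastq_bytes optional byte size of the source FASTQ (for the
#'   compression ratio); estimated from the in-memory records otherwise.
#' @return list with `collapsed` (data.frame), `qc` (see [compute_qc()]),
#'   `compressed` (see [compress_collapsed()]) and `kept` reads.
#' @export
preprocess_sample <- function(reads, cfg = preprocess_config(),
                              raw_fastq_bytes = NULL) {
  if (is.character(reads)) {
    path <- reads
    if (is.null(raw_fastq_bytes) && !grepl("\\.gz$", path))
      raw_fastq_bytes <- file.size(path)
    reads <- read_fastq(path)
  }
  n_raw <- length(reads$sequence)
  if (is.null(raw_fastq_bytes))
    raw_fastq_bytes <- sum(nchar(reads$id) + 2L * nchar(reads$sequence) + 6L)
  dropped <- c(too_short = 0L, fixed_bases = 0L, n_bases = 0L)

  keep_at <- adapter_scan(reads$sequence, cfg)
  seqs <- character(n_raw); quals <- vector("list", n_raw)
  umis <- character(n_raw); ok <- logical(n_raw)
  for (r in seq_len(n_raw)) {
    rd <- list(sequence = reads$sequence[r], quality = reads$quality[[r]])
    if (!is.na(keep_at[r])) {
      rd$sequence <- substring(rd$sequence, 1L, keep_at[r])
      rd$quality <- rd$quality[seq_len(keep_at[r])]
    }
    rd <- extract_fixed_bases(rd, cfg)
    if (is.null(rd)) { dropped[["fixed_bases"]] <- dropped[["fixed_bases"]] + 1L; next }
    rd <- quality_trim(rd, cfg)
    np <- apply_n_policy(rd$sequence, rd$quality, cfg$n_policy)
    if (is.null(np)) { dropped[["n_bases"]] <- dropped[["n_bases"]] + 1L; next }
    if (nchar(np$sequence) < cfg$min_read_len) {
      dropped[["too_short"]] <- dropped[["too_short"]] + 1L; next
    }
    seqs[r] <- np$sequence; quals[[r]] <- np$quality; umis[r] <- rd$umi; ok[r] <- TRUE
  }
  kept <- list(id = reads$id[ok], sequence = seqs[ok], quality = quals[ok])
  collapsed <- collapse_reads(kept$sequence,
                              if (cfg$umi_len > 0L) umis[ok] else NULL)
  qc <- compute_qc(reads, kept, dropped)
  list(collapsed = collapsed, qc = qc,
       compressed = compress_collapsed(collapsed, raw_fastq_bytes),
       kept = kept)
}

#' Write collapsed reads as FASTA
#'
#' Headers encode the collapsed multiplicity in the common
#' `>seq<i>_x<count>` dialect.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param path output FASTA path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  xs <- Biostrings::DNAStringSet(collapsed$sequence)
  names(xs) <- paste0("seq", seq_len(nrow(collapsed)), "_x", collapsed$count)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a collapsed-read FASTA written by [write_collapsed_fasta()]
#'
#' @param path FASTA path with `_x<count>` headers.
#' @return data.frame with `sequence` and `count`.
#' @export
read_collapsed_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  counts <- as.integer(sub(".*_x(\\d+)$", "\\1", names(xs)))
  data.frame(sequence = unname(as.character(xs)), count = counts)
}
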