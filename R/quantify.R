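## Mapping and quantification: seed-anchored ungapped alignment of collapsed
## reads, mature-miRNA counting under 5'/3' positional tolerances, isomiR
## quantification with non-templated-addition (NTA) reclassification,
## lowest-mismatch multimapper counting for other ncRNA classes, and
## miRGFF3 isoform export.

#' Mapping and counting parameters
#'
#' Defaults mirror the standard small-RNA settings: up to 5 genomic hits per
#' read, an 18-nt exact seed, one mismatch for miRNA quantification (one more
#' for isomiRs, whose terminal non-templated additions are not counted as
#' mismatches), zero mismatches for other ncRNA classes, and positional
#' tolerances of 2 nt at the 5' end and 5 nt at the 3' end around annotated
#' matures.
#'
#' @param max_hits maximum qualifying loci before a read is discarded as an
#'   over-cap multimapper.
#' @param seed_len seed length in nt; the seed must match exactly.
#' @param total_mismatches_mirna mismatch cap for miRNA counting.
#' @param total_mismatches_isomir mismatch cap at mapping time for isomiRs.
#' @param total_mismatches_other mismatch cap for other ncRNA classes.
#' @param offset5,offset3 positional tolerances (nt) at the mature 5'/3' ends.
#' @return a `mapping_params` list.
#' @export
mapping_params <- function(max_hits = 5L, seed_len = 18L,
                           total_mismatches_mirna = 1L,
                           total_mismatches_isomir = 2L,
                           total_mismatches_other = 0L,
                           offset5 = 2L, offset3 = 5L) {
  structure(list(max_hits = as.integer(max_hits),
                 seed_len = as.integer(seed_len),
                 total_mismatches_mirna = as.integer(total_mismatches_mirna),
                 total_mismatches_isomir = as.integer(total_mismatches_isomir),
                 total_mismatches_other = as.integer(total_mismatches_other),
                 offset5 = as.integer(offset5), offset3 = as.integer(offset3)),
            class = "mapping_params")
}

#' Map collapsed reads against a k-mer index
#'
#' Ungapped alignment anchored by an exact match of the read's first
#' `seed_len` bases, on both strands; mismatches beyond the seed are counted
#' and capped at `max_mismatches`. Reads with more than `max_hits` qualifying
#' loci are discarded as multimappers-over-cap; reads shorter than the seed
#' are unmapped.
#'
#' @param collapsed data.frame with `sequence` and `count`
#'   (see [collapse_reads()]).
#' @param index a `kmer_index` from [build_index()].
#' @param params a [mapping_params()].
#' @param max_mismatches total mismatch cap for this reference class.
#' @return data.frame of alignments (`sequence`, `count`, `ref_id`, `pos`
#'   0-based on the plus strand, `strand`, `mismatches`, `read_len`) with
#'   attributes `n_unmapped`, `n_multimapper` (collapsed-record counts).
#' @export
map_reads <- function(collapsed, index, params = mapping_params(),
                      max_mismatches = params$total_mismatches_mirna) {
  k <- index$k                    # the index k-mer size is the mapping seed
  seqs <- collapsed$sequence
  lens <- nchar(seqs)
  mappable <- lens >= k
  res <- list()
  n_multi <- 0L
  for (r in which(mappable)) {
    s <- seqs[r]; L <- lens[r]
    hits <- lookup_kmer(index, substring(s, 1L, k))
    if (nrow(hits) == 0L) next
    keep <- logical(nrow(hits)); mm <- integer(nrow(hits))
    pos0 <- integer(nrow(hits))
    for (h in seq_len(nrow(hits))) {
      ref <- index$seqs[[hits$ref_id[h]]]
      rl <- nchar(ref)
      if (hits$strand[h] == "+") {
        p <- hits$pos[h]
        if (p + L > rl) next
        region <- substring(ref, p + 1L, p + L)
        d <- hamming(region, s)
      } else {
        p <- hits$pos[h] + k - L
        if (p < 0L) next
        region <- revcomp(substring(ref, p + 1L, p + L))
        d <- hamming(region, s)
      }
      if (d <= max_mismatches) { keep[h] <- TRUE; mm[h] <- d; pos0[h] <- p }
    }
    nh <- sum(keep)
    if (nh == 0L) next
    if (nh > params$max_hits) { n_multi <- n_multi + 1L; next }
    res[[length(res) + 1L]] <- data.frame(
      sequence = s, count = collapsed$count[r],
      ref_id = hits$ref_id[keep], pos = pos0[keep],
      strand = hits$strand[keep], mismatches = mm[keep],
      read_len = L, stringsAsFactors = FALSE)
  }
  aln <- if (length(res)) do.call(rbind, res) else
    data.frame(sequence = character(), count = integer(),
               ref_id = character(), pos = integer(), strand = character(),
               mismatches = integer(), read_len = integer())
  n_unmapped <- nrow(collapsed) - length(unique(aln$sequence)) - n_multi
  attr(aln, "n_unmapped") <- n_unmapped
  attr(aln, "n_multimapper") <- n_multi
  aln
}

#' Count reads on annotated mature miRNAs
#'
#' A read contributes its full collapsed count to a mature `m` iff, among the
#' read's minimum-mismatch precursor alignments, an alignment satisfies
#' `|start - m.start| <= offset5`, `|end - m.end| <= offset3` and
#' `mismatches <= total_mismatches_mirna`. A read compatible with several
#' matures counts toward each.
#'
#' @param aln precursor-space alignments from [map_reads()].
#' @param matures mature annotation data.frame from a `reference_bundle`.
#' @param params a [mapping_params()].
#' @return named integer vector of counts per `mature_id`.
#' @export
count_mirnas <- function(aln, matures, params = mapping_params()) {
  counts <- setNames(integer(nrow(matures)), matures$mature_id)
  if (nrow(aln) == 0L) return(counts)
  aln <- aln[aln$strand == "+" & aln$mismatches <= params$total_mismatches_mirna, ,
             drop = FALSE]
  if (nrow(aln) == 0L) return(counts)
  best <- tapply(aln$mismatches, aln$sequence, min)
  aln <- aln[aln$mismatches == best[aln$sequence], , drop = FALSE]
  for (i in seq_len(nrow(aln))) {
    ms <- matures[matures$precursor_id == aln$ref_id[i], , drop = FALSE]
    if (nrow(ms) == 0L) next
    hit <- abs(aln$pos[i] - ms$start) <= params$offset5 &
      abs(aln$pos[i] + aln$read_len[i] - ms$end) <= params$offset3
    counts[ms$mature_id[hit]] <- counts[ms$mature_id[hit]] + aln$count[i]
  }
  counts
}

## Length of the maximal 3'-terminal run of mismatching read bases: the
## greedy NTA scan from the last base inward, stopping at the first
## templated match.
nta_length <- function(mismatch_offsets, read_len) {
  t <- 0L
  while ((read_len - t) %in% mismatch_offsets) t <- t + 1L
  t
}

#' Quantify isomiRs with NTA reclassification
#'
#' Alignments are produced with one extra mismatch allowed
#' (`total_mismatches_isomir`); terminal 3' read bases that disagree with the
#' templated precursor continuation are reclassified as non-templated
#' additions (NTA) and excluded from the mismatch count. A record is kept iff
#' the remaining internal mismatches are at most `total_mismatches_mirna` and
#' the positional tolerances hold, measured on the templated portion only.
#'
#' @param aln precursor-space alignments mapped with the isomiR cap.
#' @param matures mature annotations.
#' @param bundle the `reference_bundle` (for precursor sequences).
#' @param params a [mapping_params()].
#' @return data.frame of isomiR records: `mature_id`, `precursor_id`,
#'   `variant_label`, `sequence`, `count`, `nta`, `pos`, `templated_len`,
#'   `shift5`, `shift3`, `n_snv`.
#' @export
quantify_isomirs <- function(aln, matures, bundle, params = mapping_params()) {
  empty <- data.frame(mature_id = character(), precursor_id = character(),
                      variant_label = character(), sequence = character(),
                      count = integer(), nta = character(), pos = integer(),
                      templated_len = integer(), shift5 = integer(),
                      shift3 = integer(), n_snv = integer())
  if (nrow(aln) == 0L) return(empty)
  aln <- aln[aln$strand == "+", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(aln))) {
    pre <- bundle$precursors[[aln$ref_id[i]]]
    L <- aln$read_len[i]
    region <- substring(pre, aln$pos[i] + 1L, aln$pos[i] + L)
    mmo <- mismatch_positions(region, aln$sequence[i])
    nta_len <- nta_length(mmo, L)
    internal <- length(mmo) - nta_len
    if (internal > params$total_mismatches_mirna) next
    t_end <- aln$pos[i] + L - nta_len
    ms <- matures[matures$precursor_id == aln$ref_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ms))) {
      d5 <- aln$pos[i] - ms$start[j]
      d3 <- t_end - ms$end[j]
      if (abs(d5) > params$offset5 || abs(d3) > params$offset3) next
      nta <- if (nta_len > 0L) substring(aln$sequence[i], L - nta_len + 1L, L) else ""
      lab <- variant_label(d5, d3, internal, nta)
      out[[length(out) + 1L]] <- data.frame(
        mature_id = ms$mature_id[j], precursor_id = aln$ref_id[i],
        variant_label = lab, sequence = aln$sequence[i],
        count = aln$count[i], nta = nta, pos = aln$pos[i],
        templated_len = L - nta_len, shift5 = d5, shift3 = d3,
        n_snv = internal, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

## Canonical isomiR descriptor; "NA" for the unmodified mature form.
variant_label <- function(shift5, shift3, n_snv, nta) {
  parts <- character()
  if (shift5 != 0L) parts <- c(parts, sprintf("iso_5p:%+d", -shift5))
  if (shift3 != 0L) parts <- c(parts, sprintf("iso_3p:%+d", shift3))
  if (n_snv > 0L) parts <- c(parts, "iso_snv")
  if (nzchar(nta)) parts <- c(parts, paste0("iso_add3p:", nchar(nta)))
  if (length(parts) == 0L) "NA" else paste(parts, collapse = ",")
}

#' Count reads on a non-miRNA ncRNA class
#'
#' For each read, only alignments achieving that read's minimum mismatch
#' count contribute; each such alignment adds the read's full collapsed count
#' to its feature (no fractional splitting).
#'
#' @param aln sequence-space alignments from [map_reads()] produced with the
#'   class mismatch cap.
#' @param feature_ids feature universe (names of the class reference).
#' @return named integer vector of counts.
#' @export
count_class <- function(aln, feature_ids) {
  counts <- setNames(integer(length(feature_ids)), feature_ids)
  if (nrow(aln) == 0L) return(counts)
  best <- tapply(aln$mismatches, aln$sequence, min)
  aln <- aln[aln$mismatches == best[aln$sequence], , drop = FALSE]
  agg <- tapply(aln$count, aln$ref_id, sum)
  counts[names(agg)] <- as.integer(agg)
  counts
}

#' Assemble a count matrix from per-sample count vectors
#'
#' @param per_sample named list `sample -> named count vector`.
#' @param feature_ids optional fixed feature universe; defaults to the union.
#' @return integer matrix features x samples.
#' @export
build_count_matrix <- function(per_sample, feature_ids = NULL) {
  if (is.null(feature_ids))
    feature_ids <- sort(unique(unlist(lapply(per_sample, names))))
  m <- matrix(0L, nrow = length(feature_ids), ncol = length(per_sample),
              dimnames = list(feature_ids, names(per_sample)))
  for (s in names(per_sample)) {
    v <- per_sample[[s]]
    m[names(v), s] <- as.integer(v)
  }
  m
}

#' Write isomiR records as miRGFF3
#'
#' Emits a header-pragma'd miRGFF3 document with one feature line per isomiR
#' (`Read`, `UID`, `Name`, `Parent`, `Variant`, `Expression` attributes);
#' [read_mirgff3()] restores the records.
#'
#' @param isomirs data.frame from [quantify_isomirs()].
#' @param path output path.
#' @param sample_ids sample names for the COLDATA pragma (single-sample
#'   default).
#' @export
write_mirgff3 <- function(isomirs, path, sample_ids = "sample") {
  header <- c("## mirGFF3. VERSION 1.2",
              "## source-ontology: smallrna",
              paste0("## COLDATA: ", paste(sample_ids, collapse = ",")))
  lines <- header
  if (nrow(isomirs) > 0L) {
    type <- ifelse(isomirs$variant_label == "NA", "ref_miRNA", "isomiR")
    attrs <- paste0("UID=", isomirs$sequence,
                    ";Read=", isomirs$sequence,
                    ";Name=", isomirs$mature_id,
                    ";Parent=", isomirs$precursor_id,
                    ";Variant=", isomirs$variant_label,
                    ";Expression=", isomirs$count,
                    ";Filter=Pass")
    lines <- c(lines, paste(isomirs$precursor_id, "smallrna", type,
                            isomirs$pos + 1L,
                            isomirs$pos + isomirs$templated_len,
                            ".", "+", ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a miRGFF3 document written by [write_mirgff3()]
#'
#' @param path miRGFF3 path.
#' @return data.frame with `mature_id`, `precursor_id`, `variant_label`,
#'   `sequence`, `count`, `pos`, `templated_len`.
#' @export
read_mirgff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(mature_id = character(), precursor_id = character(),
                      variant_label = character(), sequence = character(),
                      count = integer(), pos = integer(),
                      templated_len = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  getattr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))[[1]]
    if (length(m)) m[3] else NA_character_
  }
  attrs <- vapply(f, `[`, "", 9L)
  pos1 <- as.integer(vapply(f, `[`, "", 4L))
  end1 <- as.integer(vapply(f, `[`, "", 5L))
  data.frame(
    mature_id = vapply(attrs, getattr, "", key = "Name", USE.NAMES = FALSE),
    precursor_id = vapply(f, `[`, "", 1L),
    variant_label = vapply(attrs, getattr, "", key = "Variant", USE.NAMES = FALSE),
    sequence = vapply(attrs, getattr, "", key = "Read", USE.NAMES = FALSE),
    count = as.integer(vapply(attrs, getattr, "", key = "Expression",
                              USE.NAMES = FALSE)),
    pos = pos1 - 1L, templated_len = end1 - pos1 + 1L,
    stringsAsFactors = FALSE)
}

#' Read ungapped alignments from a SAM file
#'
#' Accepts externally produced alignments (headered SAM). Only mapped,
#' ungapped records (all-`M` CIGAR) are used; mismatch counts come from the
#' `NM` tag when present and are otherwise recomputed against `refs`.
#'
#' @param path SAM file path.
#' @param refs optional named character vector of reference sequences, used
#'   to recompute mismatch counts when `NM` is absent.
#' @param counts optional named integer vector mapping read names to
#'   collapsed counts (defaults to 1 per record; `_x<count>` suffixes in
#'   read names are honoured).
#' @return alignment data.frame in the [map_reads()] layout.
#' @export
read_sam_alignments <- function(path, refs = NULL, counts = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next            # unmapped
    if (bitwAnd(flag, 2048L) > 0L) next         # supplementary
    cigar <- f[6]
    if (!grepl("^\\d+M$", cigar)) next          # ungapped only
    seq_ <- f[10]
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    read_seq <- if (strand == "-") revcomp(seq_) else seq_
    nm <- NA_integer_
    tagm <- regmatches(ln, regexec("\tNM:i:(\\d+)", ln))[[1]]
    if (length(tagm)) nm <- as.integer(tagm[2])
    pos0 <- as.integer(f[4]) - 1L
    if (is.na(nm)) {
      nm <- if (!is.null(refs) && f[3] %in% names(refs))
        hamming(substring(refs[[f[3]]], pos0 + 1L, pos0 + nchar(seq_)), seq_)
      else 0L
    }
    cnt <- 1L
    if (!is.null(counts) && f[1] %in% names(counts)) cnt <- counts[[f[1]]]
    else if (grepl("_x(\\d+)$", f[1]))
      cnt <- as.integer(sub(".*_x(\\d+)$", "\\1", f[1]))
    out[[length(out) + 1L]] <- data.frame(
      sequence = read_seq, count = cnt, ref_id = f[3], pos = pos0,
      strand = strand, mismatches = nm, read_len = nchar(seq_),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sequence = character(), count = integer(),
               ref_id = character(), pos = integer(), strand = character(),
               mismatches = integer(), read_len = integer())
}
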