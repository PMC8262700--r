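## Reference bundle: genome, miRNA precursors with mature annotations,
## per-class ncRNA references, and the k-mer seed index used for mapping.
## Internal coordinates are 0-based half-open throughout; GFF3/BED 1-based
## conventions are converted at the I/O boundary only.

NCRNA_CLASSES <- c("miRNA", "tRNA", "piRNA", "rRNA", "scaRNA", "lncRNA",
                   "snoRNA", "snRNA", "miscRNA", "circRNA")

#' Load a reference bundle
#'
#' Reads the genome, miRNA precursor sequences, mature miRNA coordinates
#' (miRBase-dialect GFF3: `miRNA` features located on precursor seqids, with
#' `Derives_from` precursor links) and per-class ncRNA references. Class
#' references may be sequence-space FASTA (as RNACentral/circBase distribute
#' piRNA/circRNA sets) or genomic GFF3/BED intervals, which are extracted to
#' sequence space against the genome (minus-strand features
#' reverse-complemented).
#'
#' @param genome_fasta genome FASTA path.
#' @param precursor_fasta miRNA precursor FASTA path.
#' @param mature_gff3 GFF3 path of mature miRNAs on precursor coordinates.
#' @param class_files named list `class -> path` of ncRNA references
#'   (`.fa`/`.fasta` treated as sequence space, `.gff3`/`.gff`/`.bed` as
#'   genomic intervals). Names must come from the supported class set.
#' @param mirna_genomic_gff3 optional GFF3 of miRNA precursor/mature loci in
#'   genome coordinates, used to categorize novel precursor candidates.
#' @return a `reference_bundle` list: `genome`, `precursors` (named character
#'   vectors), `matures` (data.frame: precursor_id, mature_id, start, end,
#'   arm; 0-based half-open), `ncrna_classes` (named list of named character
#'   sequence sets), `known_mature_seqs`, and `mirna_genomic`
#'   (a [GenomicRanges::GRanges] or `NULL`).
#' @export
load_bundle <- function(genome_fasta, precursor_fasta, mature_gff3,
                        class_files = list(), mirna_genomic_gff3 = NULL) {
  genome <- as.character(Biostrings::readDNAStringSet(genome_fasta))
  names(genome) <- sub("\\s.*$", "", names(genome))
  precursors <- as.character(Biostrings::readDNAStringSet(precursor_fasta))
  names(precursors) <- sub("\\s.*$", "", names(precursors))

  gff <- rtracklayer::import(mature_gff3, format = "gff3")
  gff <- gff[as.character(gff$type) == "miRNA"]
  matures <- data.frame(
    precursor_id = as.character(GenomicRanges::seqnames(gff)),
    mature_id = as.character(gff$Name %||% gff$ID),
    start = GenomicRanges::start(gff) - 1L,   # GFF3 1-based incl -> 0-based
    end = GenomicRanges::end(gff),            # inclusive -> half-open
    arm = vapply(as.character(gff$Name %||% gff$ID), function(n) {
      if (grepl("-5p$", n)) "5p" else if (grepl("-3p$", n)) "3p" else "unknown"
    }, "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(matures))) {
    pid <- matures$precursor_id[i]
    if (!pid %in% names(precursors))
      stop("mature ", matures$mature_id[i], " refers to unknown precursor ", pid)
    if (matures$start[i] < 0L || matures$end[i] > nchar(precursors[[pid]]) ||
        matures$start[i] >= matures$end[i])
      stop("mature ", matures$mature_id[i], " lies outside precursor ", pid)
  }

  ncrna <- list()
  for (cls in names(class_files)) {
    if (!cls %in% NCRNA_CLASSES)
      stop("unknown ncRNA class: ", cls)
    path <- class_files[[cls]]
    if (grepl("\\.(fa|fasta)(\\.gz)?$", path)) {
      s <- as.character(Biostrings::readDNAStringSet(path))
      names(s) <- sub("\\s.*$", "", names(s))
      ncrna[[cls]] <- s
    } else {
      gr <- rtracklayer::import(path)
      ncrna[[cls]] <- extract_interval_seqs(genome, gr)
    }
  }

  mirna_genomic <- NULL
  if (!is.null(mirna_genomic_gff3))
    mirna_genomic <- rtracklayer::import(mirna_genomic_gff3, format = "gff3")

  known <- character()
  for (i in seq_len(nrow(matures))) {
    known <- c(known, substring(precursors[[matures$precursor_id[i]]],
                                matures$start[i] + 1L, matures$end[i]))
  }
  structure(list(genome = genome, precursors = precursors, matures = matures,
                 ncrna_classes = ncrna,
                 known_mature_seqs = unique(known),
                 mirna_genomic = mirna_genomic),
            class = "reference_bundle")
}

## Extract sequences for genomic interval features (minus strand
## reverse-complemented); feature ids from Name/ID metadata or coordinates.
extract_interval_seqs <- function(genome, gr) {
  ids <- as.character(gr$Name %||% gr$ID %||%
                        paste0(GenomicRanges::seqnames(gr), ":",
                               GenomicRanges::start(gr)))
  out <- character(length(gr))
  for (i in seq_along(gr)) {
    contig <- as.character(GenomicRanges::seqnames(gr))[i]
    if (!contig %in% names(genome)) stop("feature on unknown contig ", contig)
    s <- substring(genome[[contig]], GenomicRanges::start(gr)[i],
                   GenomicRanges::end(gr)[i])
    if (as.character(GenomicRanges::strand(gr))[i] == "-") s <- revcomp(s)
    out[i] <- s
  }
  names(out) <- ids
  out
}

#' Write a reference bundle back to FASTA/GFF3
#'
#' Inverse of [load_bundle()] for round-trip checks and fixture export.
#'
#' @param bundle a `reference_bundle`.
#' @param dir output directory.
#' @return named list of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                precursors = file.path(dir, "precursors.fa"),
                matures = file.path(dir, "matures.gff3"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$genome),
                              paths$genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$precursors),
                              paths$precursors)
  m <- bundle$matures
  lines <- c("##gff-version 3",
             paste(m$precursor_id, "smallrna", "miRNA", m$start + 1L, m$end,
                   ".", "+", ".",
                   paste0("ID=", m$mature_id, ";Name=", m$mature_id,
                          ";Derives_from=", m$precursor_id),
                   sep = "\t"))
  writeLines(lines, paths$matures)
  for (cls in names(bundle$ncrna_classes)) {
    p <- file.path(dir, paste0(cls, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(bundle$ncrna_classes[[cls]]), p)
    paths[[cls]] <- p
  }
  if (!is.null(bundle$mirna_genomic)) {
    paths$mirna_genomic <- file.path(dir, "mirna_genomic.gff3")
    rtracklayer::export(bundle$mirna_genomic, paths$mirna_genomic,
                        format = "gff3")
  }
  invisible(paths)
}

#' Build a k-mer seed index over a reference
#'
#' Indexes every length-`k` substring of every contig on both strands. A
#' minus-strand posting stores the reverse complement of the reference
#' substring, so a read seed matching a minus posting aligns to the reverse
#' strand at that locus.
#'
#' @param seqs named character vector of reference sequences (a bundle's
#'   `genome`, `precursors`, or a class sequence set).
#' @param k seed length in nt (the mapping seed, default 18).
#' @return a `kmer_index` list with `k` and a keyed [data.table::data.table]
#'   of postings (`kmer`, `ref_id`, `pos` 0-based, `strand`).
#' @export
build_index <- function(seqs, k = 18L) {
  stopifnot(k >= 1L)
  tabs <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    n <- nchar(s)
    if (n < k) {
      warning("contig ", id, " shorter than k = ", k, "; no postings")
      next
    }
    starts <- seq_len(n - k + 1L)
    fwd <- substring(s, starts, starts + k - 1L)
    rev <- substring(revcomp(s), starts, starts + k - 1L)
    tabs[[length(tabs) + 1L]] <- data.table::data.table(
      kmer = c(fwd, rev),
      ref_id = id,
      pos = c(starts - 1L, n - k + 1L - starts),
      strand = rep(c("+", "-"), each = length(starts)))
  }
  postings <- if (length(tabs)) data.table::rbindlist(tabs) else
    data.table::data.table(kmer = character(), ref_id = character(),
                           pos = integer(), strand = character())
  data.table::setkey(postings, kmer)
  structure(list(k = as.integer(k), postings = postings,
                 ref_lengths = vapply(seqs, nchar, 0L), seqs = seqs),
            class = "kmer_index")
}

#' Look up a k-mer in a seed index
#'
#' @param index a `kmer_index` from [build_index()].
#' @param kmer a length-`k` DNA string.
#' @return data.frame of postings (`ref_id`, `pos`, `strand`); zero rows if
#'   the k-mer is absent.
#' @export
lookup_kmer <- function(index, kmer) {
  query <- data.table::data.table(kmer = kmer)   # i evaluated outside x's scope
  hits <- index$postings[query, nomatch = NULL]
  as.data.frame(hits[, c("ref_id", "pos", "strand")])
}
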