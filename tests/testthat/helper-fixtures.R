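## Shared fixture builders; everything is generated in code at test time.

## A minimal single-precursor bundle for counting tests: 70-nt precursor
## with one mature at internal coordinates [10, 32).
tiny_precursor_bundle <- function(seed = 101L) {
  set.seed(seed)
  pre <- paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE),
               collapse = "")
  structure(list(
    genome = c(chr1 = pre),
    precursors = c(pre1 = pre),
    matures = data.frame(precursor_id = "pre1", mature_id = "mat1",
                         start = 10L, end = 32L, arm = "5p",
                         stringsAsFactors = FALSE),
    ncrna_classes = list(),
    known_mature_seqs = substring(pre, 11, 32),
    mirna_genomic = NULL), class = "reference_bundle")
}

## Construct an alignment row in the map_reads() layout.
aln_row <- function(sequence, ref_id, pos, mismatches = 0L, count = 1L,
                    strand = "+") {
  data.frame(sequence = sequence, count = count, ref_id = ref_id,
             pos = as.integer(pos), strand = strand,
             mismatches = as.integer(mismatches),
             read_len = nchar(sequence), stringsAsFactors = FALSE)
}

## Reads for the discovery module: `height` copies of each planted hairpin
## arm, plus optional "decoy" stacks of reads from non-hairpin background at
## matched heights. Returns genome-space alignments.
discovery_alignments <- function(n_novel = 5L, height = 10L,
                                 n_decoys = 0L, seed = 33L,
                                 genome_len = 50000L) {
  spec <- smallrna::simulation_spec(seed = seed, n_mirnas = 5L,
                                    n_novel = n_novel,
                                    n_other = integer())
  tb <- smallrna::make_toy_bundle(spec, genome_len = genome_len)
  g <- tb$bundle$genome[[1]]
  nv <- tb$truth[!tb$truth$known, , drop = FALSE]
  seqs <- c(substring(g, nv$arm5_start + 1L, nv$arm5_end),
            substring(g, nv$arm3_start + 1L, nv$arm3_end))
  col <- data.frame(sequence = seqs, count = height)
  if (n_decoys > 0L) {
    slot_w <- genome_len %/% (nrow(tb$truth) + 1L)
    dpos <- (seq_len(n_decoys) - 1L) * slot_w + 40L   # background region
    dseqs <- c(substring(g, dpos + 1L, dpos + 22L),
               substring(g, dpos + 31L, dpos + 52L))
    col <- rbind(col, data.frame(sequence = dseqs, count = height))
  }
  idx <- smallrna::build_index(tb$bundle$genome, 18L)
  aln <- smallrna::map_reads(col, idx, smallrna::mapping_params(),
                             max_mismatches = 0L)
  list(aln = aln, bundle = tb$bundle, truth = tb$truth)
}
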