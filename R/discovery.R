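## Novel miRNA precursor discovery: local-maximum read stacks on the genome,
## dual 70-nt precursor excision per stack, hairpin folding by a weighted
## Nussinov dynamic program, Dicer-consistency scoring of read 5' ends
## against the predicted mature/star cut sites, categorization against known
## annotations, and NovoMiRank-style feature z-score ranking.

#' Discovery parameters
#'
#' @param window_len precursor excision window length W in nt (default 70).
#' @param min_stack_height minimum summed collapsed count of a read stack;
#'   raising it trades sensitivity for specificity.
#' @param mature_min_len,mature_max_len allowed mature miRNA length range.
#' @param min_dicer_fraction minimum fraction of window reads whose 5' ends
#'   fall at the mature/star cut sites (default 0.66).
#' @param boundary_tolerance cut-site tolerance in nt (default 2).
#' @param flank flank placed on the stack-distal side during excision
#'   (default 10).
#' @return a `discovery_params` list.
#' @export
discovery_params <- function(window_len = 70L, min_stack_height = 5L,
                             mature_min_len = 18L, mature_max_len = 25L,
                             min_dicer_fraction = 0.66,
                             boundary_tolerance = 2L, flank = 10L) {
  stopifnot(mature_min_len <= mature_max_len, mature_max_len < window_len)
  structure(list(window_len = as.integer(window_len),
                 min_stack_height = as.integer(min_stack_height),
                 mature_min_len = as.integer(mature_min_len),
                 mature_max_len = as.integer(mature_max_len),
                 min_dicer_fraction = min_dicer_fraction,
                 boundary_tolerance = as.integer(boundary_tolerance),
                 flank = as.integer(flank)),
            class = "discovery_params")
}

#' Find local-maximum read stacks
#'
#' Reads are grouped by shared 5' start per contig and strand (for the minus
#' strand the 5' end is the alignment end). A group is a stack iff its summed
#' collapsed count reaches `min_stack_height` and is strictly maximal among
#' groups within +/- `window_len` on the same strand; ties are broken to the
#' 5'-most group, and reported stacks never fall inside another reported
#' stack's window neighbourhood.
#'
#' @param aln genome-space alignments from [map_reads()].
#' @param params a [discovery_params()].
#' @return data.frame of stacks: `contig`, `strand`, `start`, `end`
#'   (0-based half-open genomic span of the stack reads), `height`.
#' @export
find_read_stacks <- function(aln, params = discovery_params()) {
  empty <- data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(), height = integer())
  if (nrow(aln) == 0L) return(empty)
  aln$p5 <- ifelse(aln$strand == "+", aln$pos, aln$pos + aln$read_len)
  dt <- data.table::as.data.table(aln)
  grp <- dt[, list(height = sum(count), start = min(pos),
                   end = max(pos + read_len)),
            by = c("ref_id", "strand", "p5")]
  W <- params$window_len
  out <- list()
  for (key in unique(paste(grp$ref_id, grp$strand))) {
    g <- grp[paste(grp$ref_id, grp$strand) == key]
    # candidates ordered by height desc, then 5'-most position
    ord <- order(-g$height, g$p5)
    accepted <- integer()
    for (i in ord) {
      if (g$height[i] < params$min_stack_height) next
      near <- abs(g$p5 - g$p5[i]) <= W & seq_len(nrow(g)) != i
      if (any(g$height[near] > g$height[i])) next
      ties <- which(near & g$height == g$height[i])
      if (length(ties) && any(g$p5[ties] < g$p5[i])) next
      if (length(accepted) && any(abs(g$p5[accepted] - g$p5[i]) <= W)) next
      accepted <- c(accepted, i)
    }
    if (length(accepted))
      out[[length(out) + 1L]] <- data.frame(
        contig = g$ref_id[accepted], strand = g$strand[accepted],
        start = g$start[accepted], end = g$end[accepted],
        height = g$height[accepted], stringsAsFactors = FALSE)
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res[order(res$contig, res$start), , drop = FALSE]
  } else empty
}

#' Excise two precursor candidate windows from a read stack
#'
#' Candidate A places the stack as the 5' arm of the precursor, candidate B
#' as the 3' arm; a `flank` of extra bases is left on the stack-distal side.
#' Windows extending beyond the contig are omitted; minus-strand windows are
#' reverse-complemented so the returned sequence is the precursor in 5'->3'
#' transcript orientation.
#'
#' @param stack one row of [find_read_stacks()] output.
#' @param genome named character vector of contig sequences.
#' @param params a [discovery_params()].
#' @return data.frame of up to two candidates: `contig`, `strand`,
#'   `win_start`, `win_end` (genomic, 0-based half-open), `arm_of_stack`,
#'   `sequence`.
#' @export
excise_precursors <- function(stack, genome, params = discovery_params()) {
  W <- params$window_len; fl <- params$flank
  n <- nchar(genome[[stack$contig]])
  if (stack$strand == "+") {
    wins <- list(c(stack$start - fl, stack$start - fl + W, "5p"),
                 c(stack$end + fl - W, stack$end + fl, "3p"))
  } else {
    wins <- list(c(stack$end + fl - W, stack$end + fl, "5p"),
                 c(stack$start - fl, stack$start - fl + W, "3p"))
  }
  out <- list()
  for (wn in wins) {
    a <- as.integer(wn[1]); b <- as.integer(wn[2])
    if (a < 0L || b > n) next
    s <- substring(genome[[stack$contig]], a + 1L, b)
    if (stack$strand == "-") s <- revcomp(s)
    out[[length(out) + 1L]] <- data.frame(
      contig = stack$contig, strand = stack$strand,
      win_start = a, win_end = b, arm_of_stack = wn[3],
      sequence = s, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), strand = character(),
               win_start = integer(), win_end = integer(),
               arm_of_stack = character(), sequence = character())
}

## Pairing weights of the internal folding score: GC=3, AU=2, GU=1.
pair_weight <- function(a, b) {
  w <- c(GC = 3L, CG = 3L, AT = 2L, TA = 2L, GT = 1L, TG = 1L)
  x <- unname(w[paste0(a, b)])
  ifelse(is.na(x), 0L, x)
}

#' Fold a precursor candidate into a hairpin structure
#'
#' Nested (pseudoknot-free) secondary structure maximizing the summed pair
#' weight (GC=3, AU=2, GU=1) with a minimum hairpin loop of 3 nt, computed
#' by a Nussinov-style dynamic program with traceback. The energy is the
#' negated pair-weight sum -- a unit-free stability score, more negative
#' meaning more stable; an external thermodynamic folding backend can be
#' substituted where physical kcal/mol values are needed.
#'
#' @param sequence DNA/RNA string (T and U both accepted).
#' @return list with `structure` (dot-bracket) and `energy`, or `NULL` for
#'   sequences shorter than 10 nt.
#' @export
fold_hairpin <- function(sequence) {
  n <- nchar(sequence)
  if (n < 10L) return(NULL)
  s <- strsplit(toupper(chartr("U", "T", sequence)), "")[[1]]
  wmat <- outer(s, s, pair_weight)
  M <- matrix(0L, n, n)
  # bottom-up over span lengths; min hairpin loop 3 => pair (i,j) needs j-i>=4
  for (len in 5:n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      ks <- i:(j - 4L)                           # k pairs with j, loop >= 3
      pw <- wmat[cbind(ks, rep.int(j, length(ks)))]
      left <- ifelse(ks > i, M[i, pmax(ks - 1L, 1L)], 0L)
      mid <- M[cbind(ks + 1L, rep.int(j - 1L, length(ks)))]
      cand <- left + mid + pw
      cand[pw == 0L] <- -1L
      M[i, j] <- max(M[i, j - 1L], cand)         # M[i, j-1]: j unpaired
    }
  }
  # traceback
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (j - i >= 4L) {
      if (M[i, j] == M[i, j - 1L]) { j <- j - 1L; next }
      found <- FALSE
      for (k in i:(j - 4L)) {
        pw <- wmat[k, j]
        if (pw == 0L) next
        left <- if (k > i) M[i, k - 1L] else 0L
        mid <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
        if (M[i, j] == left + mid + pw) {
          db[k] <- "("; db[j] <- ")"
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          i <- k + 1L; j <- j - 1L
          found <- TRUE; break
        }
      }
      if (!found) break
    }
  }
  list(structure = paste(db, collapse = ""), energy = -M[1, n])
}

## Pair partner table from a dot-bracket string (0s where unpaired).
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  pt <- integer(n)
  st <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") st <- c(st, i)
    else if (ch[i] == ")") {
      j <- st[length(st)]; st <- st[-length(st)]
      pt[i] <- j; pt[j] <- i
    }
  }
  pt
}

#' Assess Dicer-processing consistency of a folded candidate
#'
#' The mature arm is the stack interval mapped into window coordinates; the
#' star arm is the paired partner of the mature interval read off the fold,
#' with the canonical 2-nt 3' overhang. The Dicer fraction is the proportion
#' of window reads whose 5' ends lie within `boundary_tolerance` of the
#' mature or star 5' end. Candidates whose mature arm is unpaired in the
#' fold, whose mature length is out of range, or whose fraction is below
#' `min_dicer_fraction` are rejected.
#'
#' @param candidate one row of [excise_precursors()] output with fold
#'   results attached (`structure` column).
#' @param stack the originating stack row.
#' @param reads_in_window alignment rows whose reads fall inside the window.
#' @param params a [discovery_params()].
#' @return list with `dicer_fraction`, `mature`, `star`, `loop` (0-based
#'   half-open window-coordinate intervals) and `pass`, or `NULL` when the
#'   structure has no stem pairing the mature arm.
#' @export
assess_dicer_consistency <- function(candidate, stack, reads_in_window,
                                     params = discovery_params()) {
  W <- params$window_len
  to_win <- function(gpos) {
    if (candidate$strand == "+") gpos - candidate$win_start
    else candidate$win_end - gpos
  }
  # stack interval in window coordinates (transcript orientation)
  if (candidate$strand == "+") {
    m1 <- stack$start - candidate$win_start
    m2 <- stack$end - candidate$win_start
  } else {
    m1 <- candidate$win_end - stack$end
    m2 <- candidate$win_end - stack$start
  }
  m1 <- max(m1, 0L); m2 <- min(m2, W)
  mature_len <- m2 - m1
  if (mature_len < params$mature_min_len || mature_len > params$mature_max_len)
    return(list(pass = FALSE, reason = "mature_length",
                dicer_fraction = NA_real_, mature = c(m1, m2)))
  pt <- pair_table(candidate$structure)
  partners <- pt[(m1 + 1L):m2]
  partners <- partners[partners > 0L]
  if (length(partners) < mature_len / 2)
    return(NULL)                          # no stem pairs the mature arm
  q_lo <- min(partners) - 1L; q_hi <- max(partners)
  # hairpin quality: the mature must pair one coherent opposite arm --
  # its partner span may exceed the mature length only by small bulges,
  # and the star arm must be disjoint from the mature
  if (q_hi - q_lo > mature_len + 10L) return(NULL)
  if (min(q_hi, m2) - max(q_lo, m1) > 2L) return(NULL)
  # single stem-loop: the region spanning mature and star must contain
  # exactly one terminal loop (no bifurcating multiloop structure)
  stem_region <- substring(candidate$structure,
                           min(m1, q_lo) + 1L, max(m2, q_hi))
  n_loops <- sum(gregexpr("\\(\\.*\\)", stem_region)[[1]] > 0)
  if (n_loops != 1L) return(NULL)
  # canonical 2-nt 3' overhang on the star strand
  if (m1 >= q_hi) {                       # mature is 3' arm, star 5' arm
    star <- c(q_lo, min(q_hi + 2L, W))
    loop <- c(star[2], m1)
  } else {                                # mature is 5' arm
    star <- c(q_lo, min(q_hi + 2L, W))
    loop <- c(m2, star[1])
  }
  if (loop[1] > loop[2]) loop <- c(min(loop), min(loop))
  # read 5' ends in window coordinates
  p5g <- ifelse(reads_in_window$strand == "+", reads_in_window$pos,
                reads_in_window$pos + reads_in_window$read_len)
  p5 <- vapply(p5g, to_win, 0)
  tol <- params$boundary_tolerance
  near <- abs(p5 - m1) <= tol | abs(p5 - star[1]) <= tol
  frac <- if (length(p5)) sum(reads_in_window$count[near]) /
    sum(reads_in_window$count) else 0
  list(dicer_fraction = frac, mature = c(m1, m2), star = star, loop = loop,
       pass = frac >= params$min_dicer_fraction)
}

#' Categorize a precursor candidate against known annotations
#'
#' `novel`: no genomic overlap with known miRNA loci and the predicted
#' mature is not within edit distance 2 of any known mature sequence.
#' `known_precursor_new_mature`: the window overlaps a known precursor whose
#' opposite arm is unannotated and the stack sits on that arm.
#' `overlaps_known`: any other overlap.
#'
#' @param candidate candidate row with `contig`, `win_start`, `win_end`,
#'   `strand` and `mature_seq`.
#' @param bundle a `reference_bundle`; `bundle$mirna_genomic` (GRanges with
#'   `type` of `miRNA_primary_transcript` / `miRNA` and `Name`) supplies the
#'   known genomic loci; `bundle$known_mature_seqs` the similarity set.
#' @return one of `"novel"`, `"known_precursor_new_mature"`,
#'   `"overlaps_known"`.
#' @export
categorize_candidate <- function(candidate, bundle) {
  gr <- bundle$mirna_genomic
  similar <- FALSE
  if (length(bundle$known_mature_seqs))
    similar <- any(adist(candidate$mature_seq, bundle$known_mature_seqs) <= 2L)
  if (is.null(gr) || length(gr) == 0L)
    return(if (similar) "overlaps_known" else "novel")
  cand <- GenomicRanges::GRanges(candidate$contig,
                                 IRanges::IRanges(candidate$win_start + 1L,
                                                  candidate$win_end))
  hits <- GenomicRanges::findOverlaps(cand, gr, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(if (similar) "overlaps_known" else "novel")
  ov <- gr[S4Vectors::subjectHits(hits)]
  types <- as.character(ov$type)
  if (any(types == "miRNA"))
    return("overlaps_known")
  if (any(types == "miRNA_primary_transcript")) {
    # precursor overlap without mature overlap: new arm of a known hairpin
    return("known_precursor_new_mature")
  }
  "overlaps_known"
}

#' NovoMiRank-style candidate ranking
#'
#' Candidate features (precursor length, GC fraction, energy per nt, mature
#' length, paired-base fraction) are z-scored against a reference table of
#' known-miRNA feature means and standard deviations; the rank score is the
#' mean absolute z, so smaller is more miRNA-like.
#'
#' @param feats data.frame with columns `precursor_len`, `gc_fraction`,
#'   `energy_per_nt`, `mature_len`, `paired_fraction`.
#' @param reference data.frame with `feature`, `mean`, `sd`; defaults to the
#'   synthetic reference table shipped with the package.
#' @return numeric rank scores (one per row of `feats`).
#' @export
rank_candidates <- function(feats, reference = novomirank_reference()) {
  zsum <- numeric(nrow(feats)); nused <- 0L
  for (i in seq_len(nrow(reference))) {
    f <- reference$feature[i]
    if (!f %in% colnames(feats)) next
    if (reference$sd[i] <= 0) { warning("zero sd for feature ", f); next }
    zsum <- zsum + abs((feats[[f]] - reference$mean[i]) / reference$sd[i])
    nused <- nused + 1L
  }
  if (nused == 0L) return(rep(NA_real_, nrow(feats)))
  zsum / nused
}

#' Synthetic known-miRNA feature reference for ranking
#'
#' Feature means/sds of a toy known-miRNA set, shipped as a plain-text table
#' (synthetic; not derived from any public database snapshot).
#'
#' @return data.frame with `feature`, `mean`, `sd`.
#' @export
novomirank_reference <- function() {
  path <- system.file("extdata", "novomirank_reference_synthetic.tsv",
                      package = "smallrna")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Discover novel miRNA precursor candidates
#'
#' Full discovery pass: stacks, dual excision, folding, Dicer-consistency
#' filtering, categorization and ranking.
#'
#' @param aln genome-space alignments from [map_reads()].
#' @param bundle a `reference_bundle`.
#' @param params a [discovery_params()].
#' @return data.frame of retained candidates with coordinates, structure,
#'   energy, `dicer_fraction`, `category` and `rank_score`.
#' @export
discover_mirnas <- function(aln, bundle, params = discovery_params()) {
  stacks <- find_read_stacks(aln, params)
  out <- list()
  for (si in seq_len(nrow(stacks))) {
    stack <- stacks[si, ]
    cands <- excise_precursors(stack, bundle$genome, params)
    for (ci in seq_len(nrow(cands))) {
      cand <- cands[ci, ]
      fold <- fold_hairpin(cand$sequence)
      if (is.null(fold)) next
      cand$structure <- fold$structure
      cand$energy <- fold$energy
      inwin <- aln[aln$ref_id == cand$contig & aln$strand == cand$strand &
                     aln$pos >= cand$win_start &
                     aln$pos + aln$read_len <= cand$win_end, , drop = FALSE]
      dic <- assess_dicer_consistency(cand, stack, inwin, params)
      if (is.null(dic) || !isTRUE(dic$pass)) next
      m <- dic$mature
      cand$mature_seq <- substring(cand$sequence, m[1] + 1L, m[2])
      cand$mature_start <- m[1]; cand$mature_end <- m[2]
      cand$star_start <- dic$star[1]; cand$star_end <- dic$star[2]
      cand$dicer_fraction <- dic$dicer_fraction
      cand$category <- categorize_candidate(cand, bundle)
      out[[length(out) + 1L]] <- cand
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(), strand = character(),
                      win_start = integer(), win_end = integer(),
                      arm_of_stack = character(), sequence = character(),
                      structure = character(), energy = numeric(),
                      mature_seq = character(), mature_start = integer(),
                      mature_end = integer(), star_start = integer(),
                      star_end = integer(), dicer_fraction = numeric(),
                      category = character(), rank_score = numeric()))
  res <- do.call(rbind, out)
  pt <- lapply(res$structure, pair_table)
  feats <- data.frame(
    precursor_len = nchar(res$sequence),
    gc_fraction = vapply(res$sequence, function(s) {
      f <- Biostrings::alphabetFrequency(Biostrings::DNAString(s))
      (f[["G"]] + f[["C"]]) / sum(f[DNA_BASES])
    }, 0, USE.NAMES = FALSE),
    energy_per_nt = res$energy / nchar(res$sequence),
    mature_len = res$mature_end - res$mature_start,
    paired_fraction = vapply(pt, function(p) mean(p > 0), 0))
  res$rank_score <- rank_candidates(feats)
  res[order(res$rank_score), , drop = FALSE]
}
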