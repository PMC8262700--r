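test_that("read stacks are local maxima with minimum height and spacing", {
  # one group of 10 reads at a single position
  a <- aln_row(strrep("A", 22), "c1", 100L, count = 10L)
  st <- find_read_stacks(a, discovery_params(min_stack_height = 5))
  expect_equal(nrow(st), 1L)
  expect_equal(st$height, 10L)
  # a lower group 30 nt away inside the window is suppressed
  a2 <- rbind(aln_row(strrep("A", 22), "c1", 100L, count = 10L),
              aln_row(strrep("C", 22), "c1", 130L, count = 4L))
  st2 <- find_read_stacks(a2, discovery_params(min_stack_height = 2))
  expect_equal(nrow(st2), 1L)
  expect_equal(st2$start, 100L)
  # two equal-height groups 200 nt apart are both reported
  a3 <- rbind(aln_row(strrep("A", 22), "c1", 100L, count = 10L),
              aln_row(strrep("C", 22), "c1", 300L, count = 10L))
  expect_equal(nrow(find_read_stacks(a3, discovery_params())), 2L)
  # equal heights within the window: the 5'-most wins
  a4 <- rbind(aln_row(strrep("A", 22), "c1", 130L, count = 10L),
              aln_row(strrep("C", 22), "c1", 100L, count = 10L))
  st4 <- find_read_stacks(a4, discovery_params())
  expect_equal(st4$start, 100L)
  # below the height threshold nothing is reported
  expect_equal(nrow(find_read_stacks(a, discovery_params(min_stack_height = 11))), 0L)
})

test_that("precursor excision follows the stated interval arithmetic", {
  set.seed(81)
  g <- c(c1 = paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = ""))
  stack <- data.frame(contig = "c1", strand = "+", start = 100L, end = 122L,
                      height = 10L)
  cand <- excise_precursors(stack, g, discovery_params())
  expect_equal(cand$win_start, c(90L, 62L))
  expect_equal(cand$win_end, c(160L, 132L))
  expect_equal(cand$arm_of_stack, c("5p", "3p"))
  expect_equal(cand$sequence[1], unname(substring(g, 91, 160)))
  # stack close to the contig start: the upstream-extending window is
  # truncated and discarded, leaving a single candidate
  stack2 <- data.frame(contig = "c1", strand = "+", start = 20L, end = 42L,
                       height = 10L)
  cand2 <- excise_precursors(stack2, g, discovery_params())
  expect_equal(nrow(cand2), 1L)
  expect_equal(cand2$arm_of_stack, "5p")
  # minus strand windows are reverse-complemented
  stack3 <- data.frame(contig = "c1", strand = "-", start = 500L, end = 522L,
                       height = 10L)
  cand3 <- excise_precursors(stack3, g, discovery_params())
  expect_equal(cand3$sequence[2], revcomp(unname(substring(g, 491, 560))))
})

test_that("hairpin folding maximizes weighted pairs and matches brute force", {
  # no complementarity: open chain, energy 0
  f <- fold_hairpin("AAAAAAAAAA")
  expect_equal(f$structure, "..........")
  expect_equal(f$energy, 0)
  # 4 GC pairs around a 4-nt loop
  f <- fold_hairpin("GGGGAAAACCCC")
  expect_equal(f$structure, "((((....))))")
  expect_equal(f$energy, -12)
  # sequences below 10 nt are not folded
  expect_null(fold_hairpin("ACGUACG"))
  # DP optimum equals exhaustive enumeration; reported structure is valid
  # and achieves the optimum
  set.seed(82)
  for (i in 1:12) {
    n <- sample(10:16, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    f <- fold_hairpin(s)
    expect_equal(-f$energy, oracle_fold_score(s), info = s)
    expect_equal(structure_weight(s, f$structure), -f$energy, info = s)
  }
})

test_that("Dicer consistency counts read 5' ends at the predicted cut sites", {
  set.seed(83)
  arm <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  hp <- paste0(arm, "AAAAAAAA", revcomp(arm))
  flank <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
  win <- paste0(flank, hp, flank)     # 70 nt
  cand <- data.frame(contig = "c1", strand = "+", win_start = 0L,
                     win_end = 70L, arm_of_stack = "5p", sequence = win,
                     stringsAsFactors = FALSE)
  cand$structure <- fold_hairpin(win)$structure
  stack <- data.frame(contig = "c1", strand = "+", start = 9L, end = 31L,
                      height = 10L)
  # 8 reads at the mature 5' end, 2 scattered in the loop -> fraction 0.8
  reads <- rbind(aln_row(arm, "c1", 9L, count = 8L),
                 aln_row(strrep("A", 6), "c1", 33L, count = 2L))
  dic <- assess_dicer_consistency(cand, stack, reads, discovery_params())
  expect_equal(dic$dicer_fraction, 0.8)
  expect_true(dic$pass)
  expect_equal(dic$mature, c(9, 31))
  # all reads at the mature 5' end -> fraction 1
  dic1 <- assess_dicer_consistency(cand, stack,
                                   aln_row(arm, "c1", 9L, count = 10L),
                                   discovery_params())
  expect_equal(dic1$dicer_fraction, 1)
  # scattered reads fall below the threshold
  sc <- do.call(rbind, lapply(seq(12, 60, by = 6), function(p)
    aln_row(strrep("A", 6), "c1", p, count = 1L)))
  dic0 <- assess_dicer_consistency(cand, stack, sc, discovery_params())
  expect_false(dic0$pass)
})

test_that("candidate categories reflect overlap with known annotations", {
  # empty known set: novel
  b0 <- structure(list(known_mature_seqs = character(),
                       mirna_genomic = NULL), class = "reference_bundle")
  cand <- list(contig = "chr1", win_start = 100L, win_end = 170L,
               strand = "+", mature_seq = strrep("ACGT", 5))
  expect_equal(categorize_candidate(cand, b0), "novel")
  # predicted mature similar (edit distance <= 2) to a known mature: not novel
  b1 <- b0; b1$known_mature_seqs <- paste0(strrep("ACGT", 4), "ACGA")
  expect_equal(categorize_candidate(cand, b1), "overlaps_known")
  # overlap with a known precursor whose overlapping arm is unannotated
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(90, 90), c(200, 112)))
  gr$type <- c("miRNA_primary_transcript", "miRNA")
  gr$Name <- c("mir-x", "mir-x-5p")
  b2 <- b0; b2$mirna_genomic <- gr
  cand3p <- list(contig = "chr1", win_start = 130L, win_end = 200L,
                 strand = "+", mature_seq = strrep("TTGCA", 4))
  expect_equal(categorize_candidate(cand3p, b2), "known_precursor_new_mature")
  # overlap with an annotated mature itself
  cand5p <- list(contig = "chr1", win_start = 95L, win_end = 165L,
                 strand = "+", mature_seq = strrep("TTGCA", 4))
  expect_equal(categorize_candidate(cand5p, b2), "overlaps_known")
})

test_that("rank scores are mean absolute z against the reference table", {
  ref <- novomirank_reference()
  at_mean <- as.data.frame(as.list(setNames(ref$mean, ref$feature)))
  expect_equal(rank_candidates(at_mean), 0)
  # one feature two sd away, the rest at the mean: score 2/5
  off <- at_mean
  off$gc_fraction <- ref$mean[ref$feature == "gc_fraction"] +
    2 * ref$sd[ref$feature == "gc_fraction"]
  expect_equal(rank_candidates(off), 0.4)
  # ordering invariant under adding a constant to one feature everywhere
  two <- rbind(at_mean, off)
  r1 <- rank_candidates(two)
  shifted <- two; shifted$mature_len <- shifted$mature_len + 1
  r2 <- rank_candidates(shifted)
  expect_equal(order(r1), order(r2))
})

test_that("planted hairpins are recovered and scrambled decoys rejected", {
  fx <- discovery_alignments(n_novel = 3L, height = 10L, n_decoys = 3L,
                             seed = 84)
  cand <- discover_mirnas(fx$aln, fx$bundle,
                          discovery_params(min_stack_height = 5))
  nv <- fx$truth[!fx$truth$known, , drop = FALSE]
  hit <- vapply(seq_len(nrow(nv)), function(i)
    any(cand$win_start < nv$g_end[i] & cand$win_end > nv$g_start[i] &
          cand$dicer_fraction >= 0.8), TRUE)
  expect_true(all(hit))
  expect_true(all(cand$category[cand$dicer_fraction >= 0.8] %in%
                    c("novel", "known_precursor_new_mature", "overlaps_known")))
  # decoy stacks (no fold) produce no candidates outside hairpin loci
  in_hairpin <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(fx$truth)))
    in_hairpin <- in_hairpin |
      (cand$win_start < fx$truth$g_end[i] + 15 &
         cand$win_end > fx$truth$g_start[i] - 15)
  expect_true(all(in_hairpin))
  # raising the stack threshold never adds candidates
  cand_hi <- discover_mirnas(fx$aln, fx$bundle,
                             discovery_params(min_stack_height = 11))
  expect_lte(nrow(cand_hi), nrow(cand))
  expect_true(all(paste(cand_hi$win_start, cand_hi$arm_of_stack) %in%
                    paste(cand$win_start, cand$arm_of_stack)))
})
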