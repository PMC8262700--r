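## Independent brute-force oracles used to validate the package's optimized
## implementations. These deliberately share no code with the package paths
## they check.

## Plain Levenshtein distance via dynamic programming (utils::adist wrapper).
lev <- function(a, b) drop(utils::adist(a, b))

## Brute-force adapter occurrence scan: for every start position p, the edit
## distance is minimized over all (adapter prefix length k, segment end j)
## pairs where either the full adapter is aligned (k = la) or the read end is
## reached (j = n); coverage below min_overlap is disallowed. Returns the
## kept-prefix length (0-based trim point) or NA.
oracle_adapter_trim <- function(read, adapter, max_dist, min_overlap) {
  n <- nchar(read); la <- nchar(adapter)
  best_d <- Inf; best_p <- NA_integer_
  for (p in seq_len(max(0L, n - min_overlap + 1L))) {
    ds <- c()
    for (j in p:n) {
      seg <- substring(read, p, j)
      if (j < n) {
        if (j - p + 1L >= min_overlap) ds <- c(ds, lev(adapter, seg))
      } else {
        for (k in 0:la) ds <- c(ds, lev(substring(adapter, 1, k), seg))
      }
    }
    d <- min(ds)
    if (d <= max_dist && d < best_d) { best_d <- d; best_p <- p }
  }
  if (is.na(best_p)) NA_integer_ else best_p - 1L
}

## Brute-force ungapped mapper with exact seed: enumerates every position on
## both strands by vectorized per-base comparison. Returns a data.frame of
## (ref_id, pos, strand, mismatches) or NULL when the read is discarded as a
## multimapper-over-cap.
oracle_map_read <- function(read, refs, k, max_mm, max_hits) {
  L <- nchar(read)
  if (L < k) return(data.frame(ref_id = character(), pos = integer(),
                               strand = character(), mismatches = integer()))
  hits <- list()
  for (id in names(refs)) {
    g <- strsplit(refs[[id]], "")[[1]]
    N <- length(g)
    if (N < L) next
    np <- N - L + 1L
    for (strand in c("+", "-")) {
      r <- strsplit(if (strand == "+") read else smallrna::revcomp(read),
                    "")[[1]]
      mm <- integer(np); seed_mm <- integer(np)
      seed_idx <- if (strand == "+") 1:k else (L - k + 1L):L
      for (i in seq_len(L)) {
        neq <- g[i:(i + np - 1L)] != r[i]
        mm <- mm + neq
        if (i %in% seed_idx) seed_mm <- seed_mm + neq
      }
      ok <- which(seed_mm == 0L & mm <= max_mm)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(
          ref_id = id, pos = ok - 1L, strand = strand,
          mismatches = mm[ok], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(ref_id = character(), pos = integer(), strand = character(),
               mismatches = integer())
  if (nrow(out) > max_hits) return(NULL)
  out
}

## Textbook Benjamini-Hochberg step-up, written from the definition:
## q_(i) = min_{j >= i} m * p_(j) / j, computed on the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, m * p[o[i]] / i)
    q_sorted[i] <- min(run_min, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

## Brute-force agglomerative complete linkage: repeatedly merge the two
## clusters with the smallest maximum inter-point distance.
oracle_complete_linkage_heights <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(dm[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

## Exhaustive maximal weighted nested pairing (minimum hairpin loop 3 nt),
## top-down over "base i unpaired or paired with k" -- a different
## decomposition from the package's bottom-up "k pairs with j" DP.
oracle_fold_score <- function(sequence) {
  s <- strsplit(toupper(chartr("U", "T", sequence)), "")[[1]]
  w <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) 3L
    else if (key %in% c("AT", "TA")) 2L
    else if (key %in% c("GT", "TG")) 1L
    else 0L
  }
  n <- length(s)
  memo <- new.env(hash = TRUE)
  bf <- function(i, j) {
    if (j - i < 4L) return(0L)
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- bf(i + 1L, j)
    for (k in (i + 4L):j) {
      wk <- w(s[i], s[k])
      if (wk == 0L) next
      best <- max(best, wk + bf(i + 1L, k - 1L) + bf(k + 1L, j))
    }
    memo[[key]] <- best
    best
  }
  bf(1L, n)
}

## Exact Wilcoxon-Mann-Whitney two-sided p by full enumeration of all
## group-label assignments (no-ties case).
oracle_wmw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  vals <- c(a, b)
  combs <- utils::combn(na + nb, na)
  u_obs <- sum(rank(vals)[seq_len(na)]) - na * (na + 1) / 2
  us <- apply(combs, 2L, function(idx) {
    sum(rank(vals)[idx]) - na * (na + 1) / 2
  })
  pl <- mean(us <= u_obs); pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

## AUC by direct pair counting.
oracle_auc <- function(a, b) {
  cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  mean(cmp)
}

## Validate a dot-bracket structure: balanced, min loop 3, all pairs of
## positive weight; returns the summed pair weight.
structure_weight <- function(sequence, db) {
  s <- strsplit(toupper(chartr("U", "T", sequence)), "")[[1]]
  ch <- strsplit(db, "")[[1]]
  stopifnot(length(s) == length(ch))
  stack <- integer(); total <- 0L
  wtab <- c(GC = 3L, CG = 3L, AT = 2L, TA = 2L, GT = 1L, TG = 1L)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      stopifnot(length(stack) > 0L)
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      stopifnot(i - j >= 4L)
      wk <- unname(wtab[paste0(s[j], s[i])])
      stopifnot(!is.na(wk))
      total <- total + wk
    }
  }
  stopifnot(length(stack) == 0L)
  total
}
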