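## Detection filtering, RPM-log2 normalization, and the differential
## expression statistics suite: Shapiro-Wilk normality, Welch t,
## Wilcoxon-Mann-Whitney, ANOVA, Kruskal-Wallis, Benjamini-Hochberg FDR,
## fold changes, AUC and Cohen's d, with multi-group pairwise enumeration
## and conjunction-based candidate filtering.

#' Group design
#'
#' @param assignment named character vector `sample -> level`.
#' @param variable_name name of the annotation variable.
#' @return a `group_design` list with `assignment`, ordered `levels` and
#'   `variable_name`.
#' @export
group_design <- function(assignment, variable_name = "group") {
  stopifnot(!is.null(names(assignment)), all(nzchar(names(assignment))))
  structure(list(variable_name = variable_name,
                 assignment = assignment,
                 levels = sort(unique(unname(assignment)))),
            class = "group_design")
}

#' Detection filtering of a count matrix
#'
#' A feature counts as detected in a sample when it has at least `min_reads`
#' reads there. Features are kept when detected in at least `frac` of all
#' samples, or -- when a grouping is supplied -- in at least `frac` of the
#' samples of at least one level. Both comparisons are inclusive.
#'
#' @param counts integer matrix features x samples.
#' @param design optional [group_design()].
#' @param min_reads detection threshold in reads (default 3).
#' @param frac required detected fraction (default 0.5).
#' @return the row-filtered count matrix.
#' @export
detection_filter <- function(counts, design = NULL, min_reads = 3L,
                             frac = 0.5) {
  detected <- counts >= min_reads
  if (is.null(design)) {
    keep <- rowMeans(detected) >= frac
  } else {
    groups <- design$assignment[colnames(counts)]
    keep <- rep(FALSE, nrow(counts))
    for (lv in design$levels) {
      idx <- which(groups == lv)
      if (length(idx) == 0L) { warning("empty level ", lv); next }
      keep <- keep | rowMeans(detected[, idx, drop = FALSE]) >= frac
    }
  }
  counts[keep, , drop = FALSE]
}

#' RPM normalization and log2 transform
#'
#' `value = log2(count / depth * 1e6 + 1)` -- reads per million with a
#' pseudo-count of one before the log.
#'
#' @param counts integer matrix features x samples.
#' @param depths per-sample sequencing depths used for the RPM scale;
#'   defaults to the column sums. By default the pipeline passes each
#'   sample's total genome-mapped reads.
#' @return list with `values` (log2(RPM+1) matrix), `rpm` and `depths`.
#' @export
normalize_rpm <- function(counts, depths = colSums(counts)) {
  if (any(depths <= 0)) stop("zero sequencing depth for sample(s): ",
                             paste(colnames(counts)[depths <= 0], collapse = ", "))
  rpm <- sweep(counts, 2L, depths, "/") * 1e6
  list(values = log2(rpm + 1), rpm = rpm, depths = depths)
}

#' Enumerate all pairwise level comparisons
#'
#' For k levels, all k(k-1)/2 unordered pairs in deterministic level order.
#'
#' @param design a [group_design()].
#' @return data.frame with columns `A` and `B`.
#' @export
pairwise_comparisons <- function(design) {
  lv <- design$levels
  if (length(lv) < 2L) stop("need at least 2 levels for comparisons")
  pairs <- utils::combn(lv, 2L)
  data.frame(A = pairs[1L, ], B = pairs[2L, ], stringsAsFactors = FALSE)
}

## Area under the ROC curve, P(A > B) with ties counted 1/2 --
## the WMW U statistic scaled by n_A * n_B.
auc_stat <- function(a, b) {
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  u / (length(a) * length(b))
}

## Cohen's d with pooled (n-1 weighted) standard deviation; NA when the
## pooled sd is zero.
cohens_d_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

safe_p <- function(expr, constant_value = NA_real_) {
  tryCatch(expr, error = function(e) constant_value)
}

#' Two-group differential expression statistics for one feature
#'
#' Computes per-group Shapiro-Wilk normality p-values, the two-sided Welch
#' t-test and Wilcoxon-Mann-Whitney p-values (exact where R's implementation
#' provides it, normal approximation with continuity/tie correction
#' otherwise), the AUC (ties counted 1/2), Cohen's d on the supplied (log2)
#' scale, and the fold change of group mean RPM computed on RPM+1.
#'
#' @param a,b numeric log2(RPM+1) values of groups A and B.
#' @param rpm_a,rpm_b matching RPM-scale values (default: back-transformed).
#' @return one-row data.frame of statistics.
#' @export
test_feature <- function(a, b, rpm_a = 2^a - 1, rpm_b = 2^b - 1) {
  p_sh_a <- if (length(a) >= 3 && length(unique(a)) > 1)
    safe_p(shapiro.test(a)$p.value) else NA_real_
  p_sh_b <- if (length(b) >= 3 && length(unique(b)) > 1)
    safe_p(shapiro.test(b)$p.value) else NA_real_
  both_const <- length(unique(c(a, b))) == 1L
  p_t <- if (both_const) 1 else
    safe_p(t.test(a, b, var.equal = FALSE)$p.value)
  p_w <- if (both_const) 1 else
    safe_p(suppressWarnings(wilcox.test(a, b)$p.value))
  mean_rpm_a <- mean(rpm_a); mean_rpm_b <- mean(rpm_b)
  fc <- (mean_rpm_a + 1) / (mean_rpm_b + 1)
  data.frame(p_shapiro_A = p_sh_a, p_shapiro_B = p_sh_b,
             p_t = p_t, p_wmw = p_w,
             fold_change = fc, log2fc = log2(fc),
             auc = auc_stat(a, b), cohens_d = cohens_d_stat(a, b),
             mean_rpm_A = mean_rpm_a, mean_rpm_B = mean_rpm_b)
}

#' Multi-group tests for one feature
#'
#' One-way ANOVA (equal-variance F test) and the tie-corrected
#' Kruskal-Wallis test; only meaningful for three or more levels.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return list with `p_anova` and `p_kw` (1 when all values are identical,
#'   `NA` when undefined).
#' @export
multigroup_tests <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) == 0L)) return(list(p_anova = NA_real_, p_kw = NA_real_))
  if (length(unique(values)) == 1L) return(list(p_anova = 1, p_kw = 1))
  p_a <- safe_p(oneway.test(values ~ groups, var.equal = TRUE)$p.value)
  p_k <- safe_p(kruskal.test(values, groups)$p.value)
  list(p_anova = p_a, p_kw = p_k)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_i = min_{p_j >= p_i} (m * p_j / rank_j)` capped at
#' one; missing p-values are excluded from the family and returned as `NA`.
#' Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Differential expression analysis over a normalized matrix
#'
#' Runs [test_feature()] for every feature and every pairwise level
#' comparison, BH-adjusts the Wilcoxon-Mann-Whitney p-values per comparison
#' (the headline adjusted p), and -- for three or more levels -- adds
#' per-feature ANOVA and Kruskal-Wallis p-values.
#'
#' @param norm a list from [normalize_rpm()] (post detection filtering).
#' @param design a [group_design()].
#' @return data.frame with one row per (feature, comparison).
#' @export
de_analysis <- function(norm, design) {
  samples <- colnames(norm$values)
  groups <- design$assignment[samples]
  cmps <- pairwise_comparisons(design)
  multi <- length(design$levels) >= 3L
  res <- list()
  for (ci in seq_len(nrow(cmps))) {
    ia <- which(groups == cmps$A[ci]); ib <- which(groups == cmps$B[ci])
    rows <- lapply(rownames(norm$values), function(f) {
      st <- test_feature(norm$values[f, ia], norm$values[f, ib],
                         norm$rpm[f, ia], norm$rpm[f, ib])
      cbind(data.frame(feature_id = f, level_A = cmps$A[ci],
                       level_B = cmps$B[ci], stringsAsFactors = FALSE), st)
    })
    tab <- do.call(rbind, rows)
    tab$q_wmw <- bh_adjust(tab$p_wmw)
    tab$q_t <- bh_adjust(tab$p_t)
    res[[ci]] <- tab
  }
  out <- do.call(rbind, res)
  if (multi) {
    mg <- lapply(rownames(norm$values), function(f)
      as.data.frame(multigroup_tests(norm$values[f, ], groups)))
    mg <- do.call(rbind, mg)
    mg$feature_id <- rownames(norm$values)
    out <- merge(out, mg, by = "feature_id", sort = FALSE)
  } else {
    out$p_anova <- NA_real_; out$p_kw <- NA_real_
  }
  out[order(out$level_A, out$level_B, out$feature_id), , drop = FALSE]
}

#' Candidate filtering of DE results
#'
#' Keeps features satisfying the conjunction: mean RPM of at least `min_rpm`
#' in at least one of the two levels, AND AUC at least `min_effect` (or at
#' most `1 - min_effect`, symmetrically), AND adjusted Wilcoxon-Mann-Whitney
#' p-value below `max_p`.
#'
#' @param results data.frame from [de_analysis()].
#' @param min_rpm expression floor on the RPM scale (default 1).
#' @param min_effect AUC effect-size threshold (default 0.7).
#' @param max_p adjusted p-value ceiling (default 0.05).
#' @return the filtered rows.
#' @export
candidate_filter <- function(results, min_rpm = 1, min_effect = 0.7,
                             max_p = 0.05) {
  keep <- (pmax(results$mean_rpm_A, results$mean_rpm_B) >= min_rpm) &
    (results$auc >= min_effect | results$auc <= 1 - min_effect) &
    (!is.na(results$q_wmw) & results$q_wmw < max_p)
  results[keep, , drop = FALSE]
}

#' Volcano-plot data table
#'
#' @param results data.frame from [de_analysis()].
#' @return data.frame with `feature_id`, `log2fc` and `neg_log10_q`.
#' @export
volcano_table <- function(results) {
  data.frame(feature_id = results$feature_id,
             level_A = results$level_A, level_B = results$level_B,
             log2fc = results$log2fc,
             neg_log10_q = -log10(pmax(results$q_wmw, .Machine$double.xmin)))
}
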