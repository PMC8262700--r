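## Sample-structure exploration: PCA/UMAP embeddings, Spearman sample
## correlation, complete-linkage hierarchical clustering, top-variance
## feature subsets, and principal variance component analysis (PVCA) of
## batch effects.

#' PCA embedding of samples
#'
#' Projects samples onto the top two principal components of the
#' feature-centered expression matrix. The sign of each component is fixed by
#' making its largest-magnitude loading positive, so the embedding is fully
#' deterministic.
#'
#' @param values numeric matrix features x samples (log2(RPM+1)).
#' @return list with `coords` (samples x 2), `explained_variance` (fractions
#'   for PC1/PC2), `method = "pca"`.
#' @export
pca_embed <- function(values) {
  if (ncol(values) < 3L) stop("need at least 3 samples")
  x <- t(values)                       # samples x features
  if (all(apply(x, 2L, var) == 0)) stop("constant matrix: zero variance")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2L) coords <- cbind(coords, 0)
  for (j in 1:2) {
    if (j <= ncol(pc$rotation)) {
      load <- pc$rotation[, j]
      if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(sample_ids = colnames(values), coords = unname(coords),
       explained_variance = c(ev[1], if (length(ev) > 1) ev[2] else 0),
       method = "pca")
}

#' UMAP embedding of samples
#'
#' Two-dimensional stochastic embedding, reproducible for a fixed seed.
#' Falls back to PCA (with a warning) when there are too few samples for the
#' requested neighbourhood size.
#'
#' @param values numeric matrix features x samples.
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param seed RNG seed recorded in the output (default 42).
#' @return list with `coords`, `method`, `seed`.
#' @export
umap_embed <- function(values, n_neighbors = 15L, min_dist = 0.1, seed = 42L) {
  n <- ncol(values)
  if (n < n_neighbors + 1L) {
    if (n >= 4L) {
      warning("reducing n_neighbors to ", n - 1L, " for ", n, " samples")
      n_neighbors <- n - 1L
    } else {
      warning("too few samples for UMAP; falling back to PCA")
      out <- pca_embed(values)
      out$method <- "pca_fallback"
      return(out)
    }
  }
  if (all(values == values[, 1])) {     # degenerate: identical samples
    return(list(sample_ids = colnames(values),
                coords = matrix(0, n, 2L), method = "umap", seed = seed))
  }
  set.seed(seed)
  coords <- uwot::umap(t(values), n_neighbors = n_neighbors,
                       min_dist = min_dist, n_threads = 1L,
                       n_sgd_threads = 1L)
  list(sample_ids = colnames(values), coords = unname(coords),
       method = "umap", seed = seed)
}

#' Spearman sample-correlation matrix
#'
#' Rank correlation (ties mid-ranked) between all sample pairs of the
#' RPM-normalized expression matrix; constant samples yield `NA` entries.
#'
#' @param rpm numeric matrix features x samples on the RPM scale.
#' @return symmetric samples x samples correlation matrix, unit diagonal.
#' @export
sample_correlation <- function(rpm) {
  if (ncol(rpm) < 2L) stop("need at least 2 samples")
  cc <- suppressWarnings(cor(rpm, method = "spearman"))
  diag(cc) <- 1
  cc
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with complete linkage via [stats::hclust()],
#' returned as an explicit merge trace plus leaf order.
#'
#' @param d a [stats::dist] object or symmetric distance matrix.
#' @return list with `merges` (data.frame `a`, `b`, `height`; negative
#'   entries are leaves, positive entries earlier merges, as in
#'   [stats::hclust()]), `leaf_order`, `labels` and the `hclust` object.
#' @export
hierarchical_cluster <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  hc <- hclust(d, method = "complete")
  list(merges = data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                           height = hc$height),
       leaf_order = hc$order, labels = hc$labels, hclust = hc)
}

#' Newick-like serialization of a dendrogram
#'
#' @param hcl result of [hierarchical_cluster()].
#' @return a single newick string with merge heights as branch annotations.
#' @export
dendrogram_newick <- function(hcl) {
  hc <- hcl$hclust
  lab <- hc$labels %||% as.character(seq_len(length(hc$order)))
  node <- function(i) {
    if (i < 0) return(lab[-i])
    paste0("(", node(hc$merge[i, 1]), ",", node(hc$merge[i, 2]), "):",
           format(hc$height[i], digits = 10))
  }
  paste0(node(nrow(hc$merge)), ";")
}

#' Top-variance feature subset
#'
#' The `k` features with the largest sample variance; ties broken by feature
#' id order.
#'
#' @param values numeric matrix features x samples.
#' @param k number of features to keep.
#' @return the row-subset matrix.
#' @export
top_variance_subset <- function(values, k) {
  stopifnot(k >= 1L)
  if (k > nrow(values)) {
    warning("k exceeds feature count; returning all features")
    k <- nrow(values)
  }
  v <- apply(values, 1L, var)
  ord <- order(-v, rownames(values) %||% seq_len(nrow(values)))
  values[sort(ord[seq_len(k)]), , drop = FALSE]
}

## Method-of-moments variance-component fallback for one PC and one grouping:
## between-group mean square vs within, clipped at zero.
mom_varcomp <- function(y, g) {
  g <- factor(g)
  ni <- tabulate(g)
  gm <- tapply(y, g, mean)
  msb <- sum(ni * (gm - mean(y))^2) / max(1L, nlevels(g) - 1L)
  msw <- sum((y - gm[g])^2) / max(1L, length(y) - nlevels(g))
  n0 <- (length(y) - sum(ni^2) / length(y)) / max(1L, nlevels(g) - 1L)
  max(0, (msb - msw) / n0)
}

#' Principal variance component analysis
#'
#' Decomposes expression variance into contributions of the annotation
#' variables, their pairwise interactions, and residual noise. Features are
#' standardized to unit variance, samples are projected onto the principal
#' components retaining at least `pc_variance_threshold` of the variance,
#' and per-PC variance components are estimated by a REML mixed model with a
#' random intercept per variable and per interaction (method-of-moments
#' fallback when a fit fails). Term proportions are averaged across PCs
#' weighted by the PC eigenvalues and normalized to sum to one.
#'
#' @param values numeric matrix features x samples (log2(RPM+1)).
#' @param designs list of [group_design()] objects (annotation variables).
#' @param pc_variance_threshold cumulative PC variance to retain (default 0.6).
#' @param standardize scale features to unit variance first (default TRUE).
#' @return data.frame with `term` and `proportion`, residual last; the
#'   proportions sum to one.
#' @export
pvca <- function(values, designs, pc_variance_threshold = 0.6,
                 standardize = TRUE) {
  stopifnot(length(designs) >= 1L)
  samples <- colnames(values)
  x <- t(values)                                  # samples x features
  keep <- apply(x, 2L, var) > 0
  x <- x[, keep, drop = FALSE]
  if (standardize) x <- scale(x, center = TRUE, scale = TRUE)
  pc <- prcomp(x, center = !standardize, scale. = FALSE)
  ev <- pc$sdev^2
  nkeep <- which(cumsum(ev) / sum(ev) >= pc_variance_threshold)[1]
  nkeep <- max(1L, min(nkeep, sum(ev > 1e-12)))
  scores <- pc$x[, seq_len(nkeep), drop = FALSE]
  w <- ev[seq_len(nkeep)]

  vars <- lapply(designs, function(d) factor(d$assignment[samples]))
  names(vars) <- vapply(designs, `[[`, "", "variable_name")
  terms <- names(vars)
  inter <- list()
  if (length(vars) >= 2L) {
    cmb <- utils::combn(names(vars), 2L)
    for (j in seq_len(ncol(cmb))) {
      nm <- paste0(cmb[1, j], ":", cmb[2, j])
      inter[[nm]] <- interaction(vars[[cmb[1, j]]], vars[[cmb[2, j]]], drop = TRUE)
    }
  }
  all_terms <- c(vars, inter)

  prop <- matrix(0, nrow = length(all_terms) + 1L, ncol = nkeep,
                 dimnames = list(c(names(all_terms), "residual"), NULL))
  df <- data.frame(all_terms, check.names = FALSE)
  colnames(df) <- paste0("V", seq_along(all_terms))
  form <- stats::as.formula(paste("y ~ 1 +",
    paste(sprintf("(1|%s)", colnames(df)), collapse = " + ")))
  for (p in seq_len(nkeep)) {
    df$y <- scores[, p]
    comps <- tryCatch({
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(form, data = df,
                   control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                               check.nobs.vs.nRE = "ignore"))))
      vc <- as.data.frame(lme4::VarCorr(fit))
      v <- setNames(vc$vcov, vc$grp)
      comp <- vapply(colnames(df)[seq_along(all_terms)],
                     function(g) if (g %in% names(v)) v[[g]] else 0, 0)
      c(comp, residual = v[["Residual"]])
    }, error = function(e) {
      comp <- vapply(seq_along(all_terms),
                     function(i) mom_varcomp(df$y, all_terms[[i]]), 0)
      resid <- max(var(df$y) - sum(comp), 0)
      c(comp, residual = resid)
    })
    tot <- sum(comps)
    prop[, p] <- if (tot > 0) comps / tot else c(rep(0, length(all_terms)), 1)
  }
  avg <- as.numeric(prop %*% (w / sum(w)))
  avg <- avg / sum(avg)
  data.frame(term = rownames(prop), proportion = avg,
             stringsAsFactors = FALSE)
}
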