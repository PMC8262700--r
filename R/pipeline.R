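## Pipeline orchestration: run configuration, annotation validation, staged
## execution (preprocess -> map -> quantify -> filter/normalize -> statistics
## -> structure exploration -> discovery) and machine-readable report tables.

#' Pipeline run configuration
#'
#' @param preprocess a [preprocess_config()].
#' @param mapping a [mapping_params()].
#' @param discovery a [discovery_params()].
#' @param de_variable annotation column used for differential expression,
#'   or `NULL` to skip DE.
#' @param min_reads,detect_frac detection-filter thresholds.
#' @param top_k top-variance subset size for expression clustering.
#' @param pc_variance_threshold PVCA retained-variance threshold.
#' @param run_discovery run the novel-miRNA module (default TRUE).
#' @param seed integer seed for the stochastic stages (UMAP).
#' @return a `run_config` list.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       mapping = mapping_params(),
                       discovery = discovery_params(),
                       de_variable = NULL, min_reads = 3L, detect_frac = 0.5,
                       top_k = 50L, pc_variance_threshold = 0.6,
                       run_discovery = TRUE, seed = 42L) {
  structure(list(preprocess = preprocess, mapping = mapping,
                 discovery = discovery, de_variable = de_variable,
                 min_reads = as.integer(min_reads), detect_frac = detect_frac,
                 top_k = as.integer(top_k),
                 pc_variance_threshold = pc_variance_threshold,
                 run_discovery = run_discovery, seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a sample annotation table
#'
#' First column sample id, remaining columns categorical variables. Every
#' sample must be covered; the designated DE column needs at least two
#' non-empty levels.
#'
#' @param annotation data.frame (or TSV path) with sample ids in the first
#'   column.
#' @param samples character vector of expected sample ids.
#' @param de_variable column checked for DE usability (optional).
#' @return named list of [group_design()] objects, one per column.
#' @export
validate_annotation <- function(annotation, samples, de_variable = NULL) {
  if (is.character(annotation))
    annotation <- read.table(annotation, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  ids <- as.character(annotation[[1]])
  missing <- setdiff(samples, ids)
  if (length(missing))
    stop("annotation missing sample(s): ", paste(missing, collapse = ", "))
  designs <- list()
  for (col in colnames(annotation)[-1]) {
    v <- setNames(as.character(annotation[[col]]), ids)[samples]
    designs[[col]] <- group_design(v, variable_name = col)
  }
  if (!is.null(de_variable)) {
    if (!de_variable %in% names(designs))
      stop("DE variable ", de_variable, " not in annotation")
    lv <- designs[[de_variable]]$levels
    lv <- lv[nzchar(lv)]
    if (length(lv) < 2L)
      stop("DE variable ", de_variable, " has fewer than 2 levels")
  }
  designs
}

#' Run the full pipeline on a set of samples
#'
#' Executes preprocessing, genome/precursor/class mapping, quantification,
#' detection filtering and normalization, differential expression (when a DE
#' variable is configured), sample-structure exploration, PVCA, and novel
#' miRNA discovery, writing every result table as TSV under `output_dir`.
#' Identical inputs, configuration and seed yield byte-identical outputs.
#'
#' @param samples named list `sample -> FASTQ path or raw-read set`.
#' @param bundle a `reference_bundle`.
#' @param annotation data.frame or TSV path (first column sample id), or
#'   `NULL`.
#' @param config a [run_config()].
#' @param output_dir directory for the report bundle (created).
#' @return invisibly, a list with the in-memory results (`counts`, `norm`,
#'   `de`, `pvca`, `candidates`, `qc`, ...).
#' @export
run_pipeline <- function(samples, bundle, annotation = NULL,
                         config = run_config(), output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  sample_ids <- names(samples)
  stopifnot(length(sample_ids) >= 1L)
  designs <- NULL
  if (!is.null(annotation))
    designs <- validate_annotation(annotation, sample_ids, config$de_variable)
  else if (!is.null(config$de_variable))
    stop("DE variable configured but no annotation provided")

  ## stage 1: preprocessing
  pp <- list(); qc_rows <- list()
  for (s in sample_ids) {
    pp[[s]] <- preprocess_sample(samples[[s]], config$preprocess)
    q <- pp[[s]]$qc
    qc_rows[[s]] <- data.frame(
      sample = s, n_raw = q$n_raw, n_kept = q$n_kept,
      gc_percent = round(q$gc_percent, 4),
      compression_ratio = round(pp[[s]]$compressed$ratio, 6),
      n_dropped_too_short = q$n_dropped[["too_short"]],
      n_dropped_fixed_bases = q$n_dropped[["fixed_bases"]],
      n_dropped_n_bases = q$n_dropped[["n_bases"]])
  }
  write_tsv_table(do.call(rbind, qc_rows), file.path(output_dir, "qc.tsv"))

  ## stage 2: mapping + quantification
  k <- config$mapping$seed_len
  genome_idx <- build_index(bundle$genome, k)
  prec_idx <- build_index(bundle$precursors, k)
  class_idx <- lapply(bundle$ncrna_classes, build_index, k = k)

  depths <- integer(); map_rows <- list()
  mirna_counts <- list(); isomir_tabs <- list(); class_counts <- list()
  genome_aln_all <- list()
  for (s in sample_ids) {
    col <- pp[[s]]$collapsed
    ga <- map_reads(col, genome_idx, config$mapping,
                    max_mismatches = config$mapping$total_mismatches_mirna)
    genome_aln_all[[s]] <- ga
    gmapped <- sum(col$count[col$sequence %in% unique(ga$sequence)])
    depths[s] <- gmapped
    pa <- map_reads(col, prec_idx, config$mapping,
                    max_mismatches = config$mapping$total_mismatches_isomir)
    mirna_counts[[s]] <- count_mirnas(pa, bundle$matures, config$mapping)
    iso <- quantify_isomirs(pa, bundle$matures, bundle, config$mapping)
    iso$sample <- if (nrow(iso)) s else character(0)
    isomir_tabs[[s]] <- iso
    for (cls in names(class_idx)) {
      ca <- map_reads(col, class_idx[[cls]], config$mapping,
                      max_mismatches = config$mapping$total_mismatches_other)
      class_counts[[cls]][[s]] <- count_class(ca, names(bundle$ncrna_classes[[cls]]))
    }
    map_rows[[s]] <- data.frame(
      sample = s, n_collapsed = nrow(col),
      n_genome_mapped_reads = gmapped,
      n_multimapper_over_cap = attr(ga, "n_multimapper"),
      n_unmapped = attr(ga, "n_unmapped"))
  }
  write_tsv_table(do.call(rbind, map_rows),
                  file.path(output_dir, "mapping_stats.tsv"))

  counts <- list(miRNA = build_count_matrix(mirna_counts,
                                            bundle$matures$mature_id))
  for (cls in names(class_counts))
    counts[[cls]] <- build_count_matrix(class_counts[[cls]],
                                        names(bundle$ncrna_classes[[cls]]))
  for (cls in names(counts))
    write_tsv_table(data.frame(feature_id = rownames(counts[[cls]]),
                               counts[[cls]], check.names = FALSE),
                    file.path(output_dir, paste0("counts_", cls, ".tsv")))
  isomirs <- do.call(rbind, isomir_tabs)
  write_mirgff3(isomirs, file.path(output_dir, "isomirs.gff3"), sample_ids)

  ## stage 3: filtering, normalization, statistics, structure
  de_design <- if (!is.null(config$de_variable)) designs[[config$de_variable]]
  norm <- list(); de_tabs <- list(); pvca_tabs <- list()
  if (any(depths <= 0))
    stop("sample(s) with zero genome-mapped depth: ",
         paste(names(depths)[depths <= 0], collapse = ", "))
  for (cls in names(counts)) {
    filt <- detection_filter(counts[[cls]], de_design,
                             config$min_reads, config$detect_frac)
    if (nrow(filt) == 0L) next
    nm <- normalize_rpm(filt, depths[colnames(filt)])
    nm$values <- nm$values; norm[[cls]] <- nm
    write_tsv_table(data.frame(feature_id = rownames(nm$values),
                               round(nm$values, 6), check.names = FALSE),
                    file.path(output_dir, paste0("normalized_", cls, ".tsv")))
    if (!is.null(de_design)) {
      de <- de_analysis(nm, de_design)
      de_tabs[[cls]] <- de
      num <- vapply(de, is.numeric, TRUE)
      de_out <- de; de_out[num] <- lapply(de_out[num], signif, digits = 8)
      write_tsv_table(de_out,
                      file.path(output_dir, paste0("de_", cls, ".tsv")))
      write_tsv_table(within(volcano_table(de),
                             { log2fc <- signif(log2fc, 8)
                               neg_log10_q <- signif(neg_log10_q, 8) }),
                      file.path(output_dir, paste0("volcano_", cls, ".tsv")))
    }
    if (ncol(nm$values) >= 3L && nrow(nm$values) >= 2L) {
      emb <- pca_embed(nm$values)
      write_tsv_table(data.frame(sample = emb$sample_ids,
                                 pc1 = signif(emb$coords[, 1], 8),
                                 pc2 = signif(emb$coords[, 2], 8)),
                      file.path(output_dir, paste0("pca_", cls, ".tsv")))
      cc <- sample_correlation(nm$rpm)
      write_tsv_table(data.frame(sample = rownames(cc), round(cc, 6),
                                 check.names = FALSE),
                      file.path(output_dir, paste0("correlation_", cls, ".tsv")))
      hcl <- hierarchical_cluster(stats::dist(t(nm$values)))
      writeLines(dendrogram_newick(hcl),
                 file.path(output_dir, paste0("dendrogram_", cls, ".nwk")))
      if (!is.null(designs) && length(designs) >= 1L) {
        pv <- pvca(nm$values, designs, config$pc_variance_threshold)
        pv$proportion <- round(pv$proportion, 6)
        pvca_tabs[[cls]] <- pv
        write_tsv_table(pv, file.path(output_dir, paste0("pvca_", cls, ".tsv")))
      }
    }
  }

  ## stage 4: discovery
  candidates <- NULL
  if (isTRUE(config$run_discovery)) {
    all_aln <- do.call(rbind, genome_aln_all)
    candidates <- discover_mirnas(all_aln, bundle, config$discovery)
    cand_out <- candidates
    if (nrow(cand_out)) {
      cand_out$dicer_fraction <- round(cand_out$dicer_fraction, 6)
      cand_out$rank_score <- round(cand_out$rank_score, 6)
    }
    write_tsv_table(cand_out, file.path(output_dir, "novel_candidates.tsv"))
  }

  invisible(list(qc = pp, counts = counts, norm = norm, depths = depths,
                 isomirs = isomirs, de = de_tabs, pvca = pvca_tabs,
                 candidates = candidates, designs = designs))
}
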