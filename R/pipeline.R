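# End-to-end orchestration: QC -> normalization -> cell-cycle ->
# covariate correction -> PCA/SNN/Louvain -> markers -> enrichment ->
# superclusters -> signatures.

#' Run the full analysis chain
#'
#' @param counts count matrix (genes x cells).
#' @param read_stats data.frame: cell_id, human_reads, mouse_reads.
#' @param stage_sets stage genesets for the cell-cycle caller.
#' @param genesets optional genesets for cluster enrichment; when `NULL`
#'   the enrichment/supercluster steps are skipped.
#' @param config an `scstate_config`.
#' @param adapt_gene_band recompute the detected-gene band as 10--40% of
#'   the dataset's observed unique genes (see
#'   [gene_band_from_denominator()]); the published absolute bounds only
#'   apply to full-transcriptome data. Default `TRUE`.
#' @param markers_on `"residual"` (default) or `"lognorm"` — which matrix
#'   the marker tests run on.
#' @return list with the intermediate products: `stats`, `qc`, `expr`,
#'   `cellcycle`, `covariates`, `residuals`, `pca`, `graph`, `clusters`,
#'   `markers`, `ranked`, and when genesets are given `enrichment`,
#'   `top_sets`, `superclusters`, `cell_superclusters`, `signatures`.
#' @export
run_pipeline <- function(counts, read_stats, stage_sets, genesets = NULL,
                         config = default_config(), adapt_gene_band = TRUE,
                         markers_on = c("residual", "lognorm")) {
  markers_on <- match.arg(markers_on)
  out <- list(config = config)

  out$stats <- compute_library_stats(counts, read_stats)
  if (adapt_gene_band) {
    band <- gene_band_from_denominator(attr(out$stats, "denominator"))
    config$genes_min <- band[["genes_min"]]
    config$genes_max <- band[["genes_max"]]
    sc_log("pipeline", "gene band adapted to [", config$genes_min, ", ",
           config$genes_max, "]")
  }
  out$qc <- filter_libraries(out$stats, config)
  kept <- out$qc$cell_id[out$qc$kept]
  if (length(kept) < 10) stop("fewer than 10 cells pass QC", call. = FALSE)

  out$expr <- normalize_log(counts, kept, config)
  out$cellcycle <- call_cell_cycle(out$expr, stage_sets, config)

  stats_kept <- out$stats[out$stats$cell_id %in% kept, ]
  out$covariates <- build_covariates(out$cellcycle, stats_kept)
  out$residuals <- regress_out(out$expr, out$covariates)

  n_pcs <- min(config$n_pcs, nrow(out$residuals) - 1, ncol(out$residuals) - 1)
  out$pca <- run_pca(out$residuals, n_pcs = n_pcs)
  out$graph <- build_snn_graph(out$pca, k = config$knn_k)
  out$clusters <- cluster_louvain_cells(out$graph, seed = config$rng_seed,
                                        resolution = config$resolution)

  test_mat <- if (markers_on == "residual") out$residuals else out$expr
  sizes <- table(out$clusters$labels)
  if (length(sizes) >= 2 && all(sizes >= 2)) {
    out$markers <- find_markers(test_mat, out$clusters$labels, config)
    out$ranked <- lapply(out$markers, ranked_list)
    if (!is.null(genesets)) {
      out$enrichment <- enrich_clusters(out$ranked, genesets, config)
      out$top_sets <- top_genesets(out$enrichment,
                                   n = min(config$top_n_genesets,
                                           length(unique(out$enrichment$geneset))))
      out$superclusters <- assign_superclusters(
        out$enrichment, out$top_sets, n_super = config$n_superclusters)
      cell_sc <- out$superclusters$assignment[as.character(out$clusters$labels)]
      names(cell_sc) <- names(out$clusters$labels)
      out$cell_superclusters <- cell_sc

      sc_sizes <- table(cell_sc)
      if (length(sc_sizes) >= 2 && all(sc_sizes >= 2)) {
        pw <- pairwise_tests(test_mat, cell_sc)
        up_lists <- lapply(names(pw), function(x) {
          ups <- lapply(colnames(pw[[x]]$p), function(y) {
            tab <- data.frame(gene = rownames(pw[[x]]$p),
                              combined_p = pw[[x]]$p[, y],
                              fdr = p.adjust(pw[[x]]$p[, y], "BH"),
                              summary_lfc = pw[[x]]$lfc[, y],
                              stringsAsFactors = FALSE)
            suppressWarnings(rank_and_select(tab, fdr_thr = config$fdr_thr,
                                             top_n = config$top_n_deg,
                                             direction = "up"))
          })
          names(ups) <- colnames(pw[[x]]$p)
          ups
        })
        names(up_lists) <- names(pw)
        out$supercluster_up_lists <- up_lists
        out$signatures <- suppressWarnings(supercluster_signatures(up_lists))
      }
    }
  } else {
    sc_log("pipeline", "clustering degenerate (", length(sizes),
           " cluster(s)); marker and enrichment stages skipped")
  }
  out
}
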