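# Library-level QC: species-ratio, read-depth and detected-gene-band
# filters, then normalization of kept libraries to a fixed total and log1p.

#' Per-library statistics
#'
#' Joins the species read-count table with detected-gene counts from the
#' matrix. The PDG (percentage of detected genes) denominator defaults to
#' the number of unique genes detected in at least one library of the
#' input, and can be fixed for cross-dataset comparability.
#'
#' @param counts count matrix (genes x cells).
#' @param read_table data.frame with columns `cell_id`, `human_reads`,
#'   `mouse_reads`; must cover every cell in `counts`.
#' @param denominator optional fixed PDG denominator.
#' @return data.frame: cell_id, human_reads, mouse_reads, n_genes_detected,
#'   pdg; plus attribute `denominator`.
#' @export
compute_library_stats <- function(counts, read_table, denominator = NULL) {
  need <- c("cell_id", "human_reads", "mouse_reads")
  if (!all(need %in% names(read_table))) {
    stop("read_table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(colnames(counts), read_table$cell_id)
  if (length(missing)) {
    stop("read_table is missing cells: ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  }
  detected <- colSums(counts > 0)
  if (is.null(denominator)) denominator <- sum(rowSums(counts > 0) > 0)
  rt <- read_table[match(colnames(counts), read_table$cell_id), ]
  out <- data.frame(cell_id = colnames(counts),
                    human_reads = rt$human_reads,
                    mouse_reads = rt$mouse_reads,
                    n_genes_detected = as.integer(detected),
                    pdg = if (denominator > 0) detected / denominator else 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "denominator") <- denominator
  sc_log("qc", "stats for ", nrow(out), " cells; PDG denominator ", denominator)
  out
}

#' Apply the three library filters
#'
#' A cell is kept iff all of:
#' * species: `human_reads / mouse_reads >= species_ratio_min`
#'   (`mouse_reads == 0` with `human_reads > 0` passes);
#' * depth: `human_reads > human_reads_min` (libraries at or below the
#'   threshold are removed);
#' * gene band: `genes_min <= n_genes_detected <= genes_max` (closed band).
#'
#' The first failing filter, in that order, is recorded as the rejection
#' reason. An empty keep-set is a valid outcome.
#'
#' @param stats output of [compute_library_stats()].
#' @param config an `scstate_config`.
#' @return data.frame: cell_id, kept (logical), reason
#'   (`"species"`, `"depth"`, `"gene-band"` or `NA` for kept cells).
#' @export
filter_libraries <- function(stats, config = default_config()) {
  species_ok <- (stats$mouse_reads == 0 & stats$human_reads > 0) |
    (stats$mouse_reads > 0 &
       stats$human_reads / stats$mouse_reads >= config$species_ratio_min)
  depth_ok <- stats$human_reads > config$human_reads_min
  band_ok <- stats$n_genes_detected >= config$genes_min &
    stats$n_genes_detected <= config$genes_max
  reason <- rep(NA_character_, nrow(stats))
  reason[!band_ok] <- "gene-band"
  reason[!depth_ok] <- "depth"
  reason[!species_ok] <- "species"
  kept <- is.na(reason)
  sc_log("qc", "kept ", sum(kept), "/", nrow(stats), " cells (ratio>=",
         config$species_ratio_min, ", reads>", config$human_reads_min,
         ", genes in [", config$genes_min, ",", config$genes_max, "])")
  data.frame(cell_id = stats$cell_id, kept = kept, reason = reason,
             stringsAsFactors = FALSE)
}

#' Normalize kept libraries to a fixed total and log-transform
#'
#' Each kept cell's counts are scaled to sum to `norm_total` exactly, then
#' `log(1 + x)` is applied (natural log by default, base 2 via
#' `config$log_base = "2"`).
#'
#' @param counts count matrix.
#' @param cells cell identifiers to keep (default: all).
#' @param config an `scstate_config`.
#' @return real matrix (genes x kept cells) with attribute
#'   `provenance = "lognorm"`.
#' @export
normalize_log <- function(counts, cells = colnames(counts),
                          config = default_config()) {
  m <- counts[, cells, drop = FALSE]
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("zero-total cell(s) after filtering: ",
         paste(head(colnames(m)[totals == 0], 5), collapse = ", "), call. = FALSE)
  }
  scaled <- sweep(m, 2, config$norm_total / totals, `*`)
  out <- log1p(scaled)
  if (config$log_base == "2") out <- out / log(2)
  attr(out, "provenance") <- "lognorm"
  sc_log("qc", "normalized ", ncol(out), " cells to ", config$norm_total,
         " total, log base ", config$log_base)
  out
}
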