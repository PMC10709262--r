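# Run configuration: defaults are the published analysis parameters.

.config_defaults <- list(
  species_ratio_min = 5,        # keep: human/mouse read ratio >= 5
  human_reads_min   = 100000,   # keep: strictly more than 100k human reads
  genes_min         = 2346,     # keep: detected genes in [genes_min, genes_max]
  genes_max         = 9884,
  norm_total        = 100000,   # per-cell library size after normalization
  log_base          = "natural",# or "2"
  cor_thr           = 0.2,      # min profile correlation for a stage call
  refine_iter       = 200,      # max refinement iterations
  knn_k             = 10,
  n_pcs             = 20,
  fdr_thr           = 0.05,
  min_prop          = 0.2,      # "some" rule: DE in >= 20% of comparisons
  top_n_deg         = 250,
  top_n_genesets    = 25,
  n_superclusters   = 3,
  n_perm            = 2000,     # enrichment permutations
  weight_exp        = 1,        # GSEA weighting exponent
  resolution        = 1,        # Louvain resolution
  rng_seed          = 1
)

.config_numeric <- setdiff(names(.config_defaults), "log_base")

validate_config <- function(cfg) {
  for (key in .config_numeric) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("config: '", key, "' must be a single finite number", call. = FALSE)
    }
  }
  pos <- c("species_ratio_min", "human_reads_min", "genes_min", "genes_max",
           "norm_total", "refine_iter", "knn_k", "n_pcs", "fdr_thr",
           "min_prop", "top_n_deg", "top_n_genesets", "n_superclusters",
           "n_perm", "resolution")
  for (key in pos) {
    if (cfg[[key]] <= 0 && !(key == "refine_iter" && cfg[[key]] == 0)) {
      stop("config: '", key, "' must be positive", call. = FALSE)
    }
  }
  if (cfg$genes_min >= cfg$genes_max) {
    stop("config: genes_min must be < genes_max", call. = FALSE)
  }
  if (cfg$min_prop > 1) stop("config: min_prop must be in (0, 1]", call. = FALSE)
  if (!cfg$log_base %in% c("natural", "2")) {
    stop("config: log_base must be 'natural' or '2'", call. = FALSE)
  }
  structure(cfg, class = "scstate_config")
}

#' Default run configuration
#'
#' Returns the configuration with the published defaults: species ratio
#' >= 5, > 100k human reads, detected-gene band \[2346, 9884\],
#' normalization to 100k reads, `cor_thr = 0.2`, `refine_iter = 200`,
#' `min_prop = 0.2`, FDR 0.05, top 250 DEGs, top 25 genesets,
#' 3 superclusters.
#'
#' @return an object of class `scstate_config` (a named list).
#' @export
default_config <- function() validate_config(.config_defaults)

#' Load a run configuration from YAML with optional overrides
#'
#' @param path path to a YAML mapping of configuration keys, or `NULL`
#'   to use defaults only.
#' @param overrides named list of values that win over both defaults and
#'   file values.
#' @return validated `scstate_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .config_defaults
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("config file must be a YAML mapping", call. = FALSE)
    bad <- setdiff(names(vals), names(cfg))
    if (length(bad)) stop("config: unknown key(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg <- modifyList(cfg, vals)
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("config: unknown override(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg <- modifyList(cfg, overrides)
  }
  validate_config(cfg)
}

#' Detected-gene band from a dataset-wide gene denominator
#'
#' The published gene-band QC bounds correspond to keeping cells that
#' express roughly 10--40% of all unique genes observed across libraries.
#' This helper reproduces the lower bound (`ceiling(frac * denominator)`)
#' so the band can be rescaled to datasets of any size (for example the
#' simulator's, where the published absolute bounds would be meaningless).
#'
#' @param denominator total number of unique genes observed in the dataset.
#' @param lower_frac,upper_frac fractions defining the band (defaults
#'   0.10 and 0.40).
#' @return named numeric vector with `genes_min` and `genes_max`.
#' @export
gene_band_from_denominator <- function(denominator, lower_frac = 0.10,
                                       upper_frac = 0.40) {
  stopifnot(denominator > 0, lower_frac < upper_frac)
  c(genes_min = ceiling(lower_frac * denominator),
    genes_max = floor(upper_frac * denominator))
}
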