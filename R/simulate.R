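# Synthetic data with planted structure: donors (PDX models), latent
# biological states, a five-stage cell-cycle driving a subset of genes,
# and a per-cell capture-efficiency gradient that induces the detected-gene
# (PDG) covariate. Counts are negative binomial, thinned binomially by
# capture efficiency; mouse "contamination" is emitted only in the read
# statistics table, mirroring a fastq_screen-style species report.

#' Describe a simulated dataset
#'
#' Defaults are the standard design used throughout the test-suite:
#' 2000 genes x 500 cells, 3 donors, 3 latent states with log-fold-change
#' 1.0 on 5% of genes each, 15% cycle-regulated genes with amplitude 1.5,
#' capture efficiency uniform on (0.2, 0.6).
#'
#' @param n_genes,n_cells matrix dimensions.
#' @param n_donors number of donors (PDX models); each gets i.i.d. normal
#'   per-gene log-scale offsets with sd `donor_effect_sd`.
#' @param donor_effect_sd log-scale sd of donor offsets.
#' @param n_states number of latent biological states (>= 1).
#' @param state_marker_frac fraction of genes that are markers of each state.
#' @param state_logfc log fold change planted on marker genes (natural log);
#'   80% of markers are up, 20% down in their state.
#' @param cycle_gene_frac fraction of genes that are cycle-regulated.
#' @param cycle_amplitude log-scale amplitude of the cosine cycle effect.
#' @param pdg_range two-element capture-efficiency interval within (0, 1].
#' @param baseline_mean mean baseline counts per gene (lognormal across genes).
#' @param dispersion negative-binomial dispersion (1/size); > 0.
#' @param mouse_contam_frac fraction of libraries flagged mouse-dominated in
#'   the read table.
#' @param seed RNG seed; same seed gives bit-identical output.
#' @return validated `simulation_design` list.
#' @export
simulation_design <- function(n_genes = 2000, n_cells = 500, n_donors = 3,
                              donor_effect_sd = 0.15, n_states = 3,
                              state_marker_frac = 0.05, state_logfc = 1.0,
                              cycle_gene_frac = 0.15, cycle_amplitude = 1.5,
                              pdg_range = c(0.2, 0.6), baseline_mean = 2,
                              dispersion = 0.4, mouse_contam_frac = 0.05,
                              seed = 1) {
  d <- as.list(environment())
  fr <- c("state_marker_frac", "cycle_gene_frac", "mouse_contam_frac")
  for (key in fr) if (d[[key]] < 0 || d[[key]] > 1)
    stop("design: '", key, "' must be in [0, 1]", call. = FALSE)
  if (d$n_states < 1) stop("design: n_states must be >= 1", call. = FALSE)
  if (length(pdg_range) != 2 || pdg_range[1] <= 0 || pdg_range[2] > 1 ||
      pdg_range[1] > pdg_range[2])
    stop("design: pdg_range must be within (0, 1]", call. = FALSE)
  if (d$dispersion <= 0) stop("design: dispersion must be > 0", call. = FALSE)
  if (d$cycle_amplitude < 0) stop("design: cycle_amplitude must be >= 0", call. = FALSE)
  structure(d, class = "simulation_design")
}

#' Simulate a count matrix with planted structure
#'
#' Expected log expression of gene g in cell c is
#' `log(baseline_g) + donor_effect[g, donor_c] + state_effect[g, state_c] +
#' cycle_amplitude * cos(theta_c - peak_g)` (the last term for
#' cycle-regulated genes only). Counts are drawn negative-binomially from
#' that mean and thinned binomially by the cell's capture efficiency,
#' which induces the detected-gene (PDG) gradient. Cycle genes are binned
#' by peak phase into five equal 72-degree arcs labelled with [CC_STAGES],
#' giving the stage genesets a cell-cycle caller needs.
#'
#' @param design a [simulation_design()].
#' @return list of class `scstate_sim` with elements
#'   `counts` (gene x cell matrix), `read_stats` (data.frame: cell_id,
#'   human_reads, mouse_reads), `truth` (list with `cells` and `genes`
#'   data.frames), and `stage_sets` (GMT-style named list).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  G <- design$n_genes; N <- design$n_cells
  genes <- sprintf("G%05d", seq_len(G))
  cells <- sprintf("C%05d", seq_len(N))

  baseline <- rlnorm(G, meanlog = log(design$baseline_mean) - 0.5, sdlog = 1)

  donor <- sample(rep_len(seq_len(design$n_donors), N))
  donor_eff <- matrix(rnorm(G * design$n_donors, sd = design$donor_effect_sd),
                      nrow = G)

  state <- sample(rep_len(seq_len(design$n_states), N))

  # disjoint gene roles: cycle genes first, then one marker block per state.
  # Roles are planted on the expressed half of the transcriptome (baseline
  # above the median): a cycle gene or state marker that is transcriptionally
  # silent is not a marker in any biological sense.
  n_cycle <- round(design$cycle_gene_frac * G)
  n_cycle <- 5 * (n_cycle %/% 5)              # equal-sized stage arcs
  n_mark <- round(design$state_marker_frac * G)
  eligible <- which(baseline >= stats::median(baseline))
  if (n_cycle + design$n_states * n_mark > length(eligible)) {
    stop("design plants more cycle/marker genes than expressed genes available",
         call. = FALSE)
  }
  pool <- sample(eligible)
  cycle_idx <- pool[seq_len(n_cycle)]
  pool <- pool[-seq_len(n_cycle)]
  marker_idx <- vector("list", design$n_states)
  for (s in seq_len(design$n_states)) {
    marker_idx[[s]] <- pool[seq_len(n_mark)]
    pool <- pool[-seq_len(n_mark)]
  }

  # cycle genes: stage sector (72 deg each), peak uniform within sector
  sector <- rep(seq_len(5), each = n_cycle %/% 5)
  arc <- 2 * pi / 5
  peak <- (sector - 1) * arc + runif(n_cycle, 0, arc)

  theta <- runif(N, 0, 2 * pi)
  capture <- runif(N, design$pdg_range[1], design$pdg_range[2])

  log_mu <- matrix(log(baseline), G, N) + donor_eff[, donor]
  for (s in seq_len(design$n_states)) {
    idx <- marker_idx[[s]]
    if (length(idx)) {
      sign_s <- sample(c(1, -1), length(idx), replace = TRUE,
                       prob = c(0.8, 0.2))
      log_mu[idx, state == s] <- log_mu[idx, state == s] +
        sign_s * design$state_logfc
      marker_idx[[s]] <- list(idx = idx, logfc = sign_s * design$state_logfc)
    } else {
      marker_idx[[s]] <- list(idx = integer(0), logfc = numeric(0))
    }
  }
  if (n_cycle) {
    log_mu[cycle_idx, ] <- log_mu[cycle_idx, ] +
      design$cycle_amplitude * cos(outer(peak, theta, function(p, t) t - p))
  }

  size <- 1 / design$dispersion
  counts <- matrix(rnbinom(G * N, mu = exp(log_mu), size = size), G, N)
  counts <- matrix(rbinom(G * N, counts, rep(capture, each = G)), G, N)
  counts <- count_matrix(counts, genes, cells)

  # read statistics: human reads scale with captured counts, normalised so
  # the expected per-cell depth is ~400k whatever the transcriptome size
  # (C1-style depth, comfortably above the 100k QC floor); a fraction of
  # libraries is emitted as mouse-dominated (ratio below any sane cutoff)
  total <- colSums(counts)
  expected_total <- design$baseline_mean * G * mean(design$pdg_range)
  reads_per_count <- 4e5 / expected_total
  human <- round(total * reads_per_count * runif(N, 0.9, 1.1))
  contam <- rep(FALSE, N)
  n_contam <- round(design$mouse_contam_frac * N)
  if (n_contam > 0) contam[sample.int(N, n_contam)] <- TRUE
  mouse <- integer(N)
  mouse[contam] <- round(human[contam] / runif(sum(contam), 0.5, 4))
  clean <- which(!contam)
  hi_ratio <- runif(length(clean), 50, 500)
  mouse[clean] <- round(human[clean] / hi_ratio)
  mouse[clean][seq_along(clean) %% 10 == 0] <- 0   # some libraries see no mouse

  stage_sets <- split(genes[cycle_idx], CC_STAGES[sector])
  stage_sets <- stage_sets[CC_STAGES[CC_STAGES %in% names(stage_sets)]]

  gene_truth <- data.frame(
    gene = genes, is_cycle = FALSE, peak_phase = NA_real_,
    state = NA_integer_, marker_logfc = NA_real_, stringsAsFactors = FALSE)
  gene_truth$is_cycle[cycle_idx] <- TRUE
  gene_truth$peak_phase[cycle_idx] <- peak
  for (s in seq_len(design$n_states)) {
    gene_truth$state[marker_idx[[s]]$idx] <- s
    gene_truth$marker_logfc[marker_idx[[s]]$idx] <- marker_idx[[s]]$logfc
  }

  cell_truth <- data.frame(
    cell_id = cells, donor = donor, state = state, theta_true = theta,
    capture = capture, species = ifelse(contam, "mouse", "human"),
    stringsAsFactors = FALSE)

  sc_log("simulate", G, " genes x ", N, " cells, ", design$n_donors,
         " donors, ", design$n_states, " states, seed ", design$seed)
  structure(list(counts = counts,
                 read_stats = data.frame(cell_id = cells, human_reads = human,
                                         mouse_reads = mouse,
                                         stringsAsFactors = FALSE),
                 truth = list(cells = cell_truth, genes = gene_truth),
                 stage_sets = stage_sets,
                 design = design),
            class = "scstate_sim")
}

#' True stage sector of each simulated cell
#'
#' Bins `theta_true` into the five equal arcs used for the stage genesets.
#' @param sim an `scstate_sim`.
#' @return character vector of [CC_STAGES] labels.
#' @export
true_stage <- function(sim) {
  CC_STAGES[pmin(5, floor(sim$truth$cells$theta_true / (2 * pi / 5)) + 1)]
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits `<prefix>.mtx` (+ `.genes.txt` / `.cells.txt`),
#' `<prefix>_read_stats.csv`, `<prefix>_stages.gmt`,
#' `<prefix>_truth_cells.csv` and `<prefix>_truth_genes.csv`, so the CLI
#' stages can be exercised black-box. Re-running with the same design
#' yields byte-identical files.
#'
#' @param sim an `scstate_sim`.
#' @param prefix output path prefix.
#' @return invisibly, a character vector of file paths.
#' @export
write_fixture <- function(sim, prefix) {
  stopifnot(inherits(sim, "scstate_sim"))
  paths <- c(write_count_matrix(sim$counts, paste0(prefix, ".mtx")))
  p <- paste0(prefix, "_read_stats.csv")
  write.csv(sim$read_stats, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_stages.gmt")
  write_gmt(sim$stage_sets, p)
  paths <- c(paths, p)
  p <- paste0(prefix, "_truth_cells.csv")
  write.csv(sim$truth$cells, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_truth_genes.csv")
  write.csv(sim$truth$genes, p, row.names = FALSE, quote = FALSE)
  invisible(c(paths, p))
}
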