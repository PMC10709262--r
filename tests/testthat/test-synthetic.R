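test_that("design validation enforces the stated invariants", {
  expect_error(simulation_design(cycle_gene_frac = 1.2), "cycle_gene_frac")
  expect_error(simulation_design(n_states = 0), "n_states")
  expect_error(simulation_design(pdg_range = c(0, 0.5)), "pdg_range")
  expect_error(simulation_design(dispersion = 0), "dispersion")
})

test_that("generator output satisfies its structural invariants", {
  sim <- standard_sim()
  d <- sim$design
  expect_equal(dim(sim$counts), c(d$n_genes, d$n_cells))
  expect_true(all(sim$counts >= 0))
  ct <- sim$truth$cells
  expect_identical(ct$cell_id, colnames(sim$counts))
  expect_true(all(ct$theta_true >= 0 & ct$theta_true < 2 * pi))
  expect_true(all(ct$state %in% seq_len(d$n_states)))
  expect_true(all(ct$donor %in% seq_len(d$n_donors)))
  expect_equal(sum(ct$species == "mouse"), round(d$mouse_contam_frac * d$n_cells))
  # mouse-flagged libraries sit below the species threshold, others above
  rs <- sim$read_stats
  ratio <- rs$human_reads / pmax(rs$mouse_reads, 1)
  expect_true(all(ratio[ct$species == "mouse"] < 5))
  expect_true(all(rs$mouse_reads[ct$species == "human"] == 0 |
                    ratio[ct$species == "human"] >= 5))
  # stage sets: five arcs, one per stage, disjoint, covering all cycle genes
  expect_identical(names(sim$stage_sets), CC_STAGES)
  members <- unlist(sim$stage_sets)
  expect_false(anyDuplicated(members) > 0)
  expect_setequal(members, sim$truth$genes$gene[sim$truth$genes$is_cycle])
  # peak phases lie inside their stage's 72-degree sector
  gt <- sim$truth$genes[sim$truth$genes$is_cycle, ]
  sector <- findInterval(gt$peak_phase, seq(0, 2 * pi, by = 2 * pi / 5),
                         rightmost.closed = TRUE)
  expect_identical(CC_STAGES[sector],
                   unname(rep(names(sim$stage_sets),
                              lengths(sim$stage_sets))[
                     match(gt$gene, unlist(sim$stage_sets))]))
})

test_that("same seed is bit-identical; fixtures round-trip byte-identically", {
  a <- simulate_dataset(simulation_design(n_genes = 200, n_cells = 40, seed = 5))
  b <- simulate_dataset(simulation_design(n_genes = 200, n_cells = 40, seed = 5))
  expect_identical(a$counts, b$counts)
  expect_identical(a$read_stats, b$read_stats)
  expect_identical(a$truth, b$truth)

  dir <- withr::local_tempdir()
  f1 <- write_fixture(a, file.path(dir, "run1"))
  f2 <- write_fixture(b, file.path(dir, "run2"))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  back <- read_count_matrix(file.path(dir, "run1.mtx"))
  expect_identical(back, a$counts * 1)
  truth_cells <- read.csv(file.path(dir, "run1_truth_cells.csv"))
  expect_equal(nrow(truth_cells), 40)
})

test_that("detected-gene fraction tracks the planted capture efficiency", {
  sim <- standard_sim()
  stats <- compute_library_stats(sim$counts, sim$read_stats)
  frac <- stats$n_genes_detected / attr(stats, "denominator")
  rng <- sim$design$pdg_range
  # mean detected fraction within pdg_range +/- 0.05
  expect_gt(mean(frac), rng[1] - 0.05)
  expect_lt(mean(frac), rng[2] + 0.05)
  # thinning law: detection increases with true capture efficiency
  capture <- sim$truth$cells$capture
  expect_gt(cor(frac, capture, method = "spearman"), 0.9)
  bins <- cut(capture, quantile(capture, 0:5 / 5), include.lowest = TRUE)
  expect_false(is.unsorted(tapply(frac, bins, mean)))
})

test_that("zero cycle amplitude gives chance-level stage recovery", {
  sim <- simulate_dataset(simulation_design(cycle_amplitude = 0, seed = 2))
  expr <- normalize_log(sim$counts)
  cc <- call_cell_cycle(expr, sim$stage_sets)
  ts <- true_stage(sim)
  asn <- cc$stage != "unassigned"
  acc <- mean(cc$stage[asn] == ts[asn])
  expect_lt(abs(acc - 0.2), 0.15)
})

test_that("null design yields no reproducible multi-cluster structure", {
  # With one state and no donor effect, residual clusters are geometry of
  # noise: clusterings from two disjoint gene halves should not agree.
  # (A kNN graph of pure noise still has modularity well above a
  # degree-matched random graph, so modularity itself is not the witness.)
  sim <- simulate_dataset(simulation_design(n_states = 1, donor_effect_sd = 0,
                                            seed = 3))
  expr <- normalize_log(sim$counts)
  cc <- call_cell_cycle(expr, sim$stage_sets)
  stats <- compute_library_stats(sim$counts, sim$read_stats)
  resid <- regress_out(expr, build_covariates(cc, stats))
  half <- seq_len(nrow(resid)) %% 2 == 0
  cl1 <- cluster_louvain_cells(
    build_snn_graph(run_pca(resid[half, ], 10), 10), seed = 1)
  cl2 <- cluster_louvain_cells(
    build_snn_graph(run_pca(resid[!half, ], 10), 10), seed = 1)
  expect_lt(adjusted_rand_index(cl1$labels, cl2$labels), 0.1)
})

test_that("cluster recovery is monotone in the planted state effect", {
  ari_at <- function(lfc) {
    sim <- simulate_dataset(simulation_design(n_genes = 1000, n_cells = 300,
                                              state_logfc = lfc, seed = 11))
    expr <- normalize_log(sim$counts)
    cc <- call_cell_cycle(expr, sim$stage_sets)
    stats <- compute_library_stats(sim$counts, sim$read_stats)
    resid <- regress_out(expr, build_covariates(cc, stats))
    cl <- cluster_louvain_cells(build_snn_graph(run_pca(resid, 20), 10),
                                seed = 1)
    adjusted_rand_index(cl$labels, sim$truth$cells$state)
  }
  aris <- vapply(c(0.25, 1, 2), ari_at, numeric(1))
  expect_true(all(diff(aris) >= -1e-8))
})
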