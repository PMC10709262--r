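# shared fixtures; the standard simulated design is cached per session
# because several files exercise it

.fixture_cache <- new.env(parent = emptyenv())

standard_sim <- function(seed = 1) {
  key <- paste0("sim", seed)
  if (!exists(key, .fixture_cache)) {
    assign(key, simulate_dataset(simulation_design(seed = seed)), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# small deterministic count matrix for io/qc unit tests
tiny_counts <- function() {
  count_matrix(matrix(c(5, 0, 0, 0, 0, 2), nrow = 3, byrow = TRUE),
               genes = c("g1", "g2", "g3"), cells = c("c1", "c2"))
}

# genesets for the planted states plus random decoys, for enrichment tests
state_genesets <- function(sim, n_decoys = 5, decoy_size = 80, seed = 99) {
  gt <- sim$truth$genes
  states <- sort(unique(gt$state[!is.na(gt$state)]))
  sets <- lapply(states, function(s)
    gt$gene[!is.na(gt$state) & gt$state == s & gt$marker_logfc > 0])
  names(sets) <- paste0("STATE_", states)
  set.seed(seed)
  decoys <- lapply(seq_len(n_decoys), function(i) sample(gt$gene, decoy_size))
  names(decoys) <- paste0("RANDOM_", seq_len(n_decoys))
  c(sets, decoys)
}

# brute-force ES oracle: direct enumeration of the running-sum walk,
# independent of the package implementation
es_oracle <- function(scores, geneset, weight_exp = 1) {
  hit <- names(scores) %in% geneset
  N <- length(scores); Nh <- sum(hit)
  w <- abs(scores)^weight_exp
  nr <- sum(w[hit])
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (nr > 0) unname(w[i]) / nr else 1 / Nh
    } else {
      -1 / (N - Nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# weighted modularity computed from first principles (labels + edge list)
modularity_oracle <- function(graph, labels) {
  el <- igraph::as_data_frame(graph)
  if (is.null(el$weight)) el$weight <- 1
  m <- sum(el$weight)
  deg <- setNames(rep(0, length(labels)), names(labels))
  for (i in seq_len(nrow(el))) {
    deg[el$from[i]] <- deg[el$from[i]] + el$weight[i]
    deg[el$to[i]] <- deg[el$to[i]] + el$weight[i]
  }
  q <- 0
  for (cl in unique(labels)) {
    members <- names(labels)[labels == cl]
    within <- sum(el$weight[el$from %in% members & el$to %in% members])
    q <- q + within / m - (sum(deg[members]) / (2 * m))^2
  }
  q
}
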