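# Dimensionality reduction, shared-nearest-neighbour graph and Louvain
# community detection — the clustering engine applied before and after
# covariate correction.

#' Principal-component embedding of cells
#'
#' Cells are observations, genes variables; genes are centred (optionally
#' unit-variance scaled; zero-variance genes are excluded from scaling) and
#' decomposed by SVD. Component signs are fixed so each component's
#' largest-magnitude gene loading is positive, making the embedding
#' deterministic.
#'
#' @param mat genes x cells matrix (log-normalized or residual).
#' @param n_pcs number of components; must be < min(n_genes, n_cells).
#' @param scale_genes scale genes to unit variance before the SVD.
#' @return cells x n_pcs score matrix with attributes `sdev` (component
#'   standard deviations) and `rotation` (gene loadings).
#' @export
run_pca <- function(mat, n_pcs = 20, scale_genes = FALSE) {
  X <- t(mat)
  if (n_pcs >= min(dim(X))) {
    stop("n_pcs must be smaller than both the gene and cell counts", call. = FALSE)
  }
  if (scale_genes) {
    keep <- apply(X, 2, sd) > 0
    X <- X[, keep, drop = FALSE]
  }
  pr <- prcomp(X, center = TRUE, scale. = scale_genes, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(k) {
    load <- pr$rotation[, k]
    sign(load[which.max(abs(load))]) < 0
  }, logical(1))
  pr$x[, flip] <- -pr$x[, flip]
  pr$rotation[, flip] <- -pr$rotation[, flip]
  scores <- pr$x
  attr(scores, "sdev") <- pr$sdev
  attr(scores, "rotation") <- pr$rotation
  sc_log("cluster", "PCA: ", ncol(mat), " cells -> ", ncol(scores), " PCs")
  scores
}

#' Shared-nearest-neighbour graph with Jaccard weights
#'
#' Each cell's neighbourhood is itself plus its `k` nearest neighbours by
#' Euclidean distance (distance ties broken by cell index). Two cells are
#' connected iff their neighbourhoods intersect, with weight
#' `|N(i) intersect N(j)| / |N(i) union N(j)|`.
#'
#' @param emb cells x d embedding matrix (rownames = cell ids).
#' @param k number of nearest neighbours (`0 < k < n_cells`).
#' @return an undirected [igraph::graph] with `weight` edge attribute and
#'   cell-id vertex names.
#' @export
build_snn_graph <- function(emb, k = 10) {
  n <- nrow(emb)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  if (is.null(rownames(emb))) rownames(emb) <- as.character(seq_len(n))
  d <- as.matrix(dist(emb))
  # membership matrix: M[i, j] = 1 iff j is in N(i) = {i} + kNN(i)
  nb <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, -i], seq_len(n)[-i])  # ties by index
    c(i, seq_len(n)[-i][ord[seq_len(k)]])
  }, integer(k + 1)))
  M <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1),
                            j = as.vector(t(nb)), x = 1, dims = c(n, n))
  shared <- as(as(Matrix::triu(Matrix::tcrossprod(M), k = 1), "generalMatrix"),
               "TsparseMatrix")
  inter <- shared@x
  w <- inter / (2 * (k + 1) - inter)
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(emb)[shared@i + 1L],
               to = rownames(emb)[shared@j + 1L],
               weight = w),
    directed = FALSE,
    vertices = data.frame(name = rownames(emb)))
  sc_log("cluster", "SNN graph: ", n, " cells, ", igraph::ecount(g),
         " edges, k = ", k)
  g
}

#' Louvain community detection
#'
#' Two-phase greedy modularity maximization on the weighted graph. The
#' sweep order is randomised, so the RNG seed fixes the result exactly.
#' A graph with no edges yields one singleton cluster per cell.
#'
#' @param graph weighted undirected graph from [build_snn_graph()].
#' @param seed integer RNG seed.
#' @param resolution Louvain resolution (default 1).
#' @return list: `labels` (integer cluster ids, contiguous from 0, named
#'   by cell) and `modularity` of the returned partition.
#' @export
cluster_louvain_cells <- function(graph, seed = 1, resolution = 1) {
  set.seed(seed)
  if (igraph::ecount(graph) == 0) {
    sc_log("cluster", "graph has no edges; every cell its own cluster")
    labels <- seq_len(igraph::vcount(graph)) - 1L
    names(labels) <- igraph::V(graph)$name
    return(list(labels = labels, modularity = 0))
  }
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  labels <- as.integer(igraph::membership(cl)) - 1L
  names(labels) <- igraph::V(graph)$name
  sc_log("cluster", "Louvain: ", length(unique(labels)), " clusters, ",
         "modularity ", round(max(cl$modularity), 4))
  list(labels = labels, modularity = max(cl$modularity))
}

#' Cluster composition against per-cell annotations
#'
#' For every annotation column (stage, PDG bin, donor, site, ...) returns
#' per-cluster counts and fractions per level plus the Shannon entropy of
#' the cluster's composition, and the mean entropy across clusters.
#'
#' @param labels named cluster labels (from [cluster_louvain_cells()]).
#' @param annotations data.frame with a `cell_id` column plus one column
#'   per annotation; must cover all labelled cells.
#' @return named list per annotation: `counts`, `fractions` (clusters x
#'   levels), `entropy` (per cluster), `mean_entropy`.
#' @export
composition_table <- function(labels, annotations) {
  unknown <- setdiff(names(labels), annotations$cell_id)
  if (length(unknown)) {
    stop("annotations missing for cell(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  ann <- annotations[match(names(labels), annotations$cell_id), , drop = FALSE]
  out <- lapply(setdiff(names(ann), "cell_id"), function(col) {
    tab <- table(cluster = labels, level = ann[[col]])
    frac <- tab / rowSums(tab)
    ent <- apply(tab, 1, shannon_entropy)
    list(counts = unclass(tab), fractions = unclass(frac), entropy = ent,
         mean_entropy = mean(ent))
  })
  names(out) <- setdiff(names(ann), "cell_id")
  out
}
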