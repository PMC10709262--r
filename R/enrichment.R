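# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running-sum
# enrichment score, gene-permutation NES and p-values, top-|NES| geneset
# selection, hierarchical supercluster assignment and supercluster
# signature extraction.

check_ranked <- function(scores) {
  if (is.null(names(scores))) stop("ranked list must be named", call. = FALSE)
  if (anyDuplicated(names(scores))) stop("ranked list has duplicate genes",
                                         call. = FALSE)
  if (any(!is.finite(scores))) stop("ranked list has non-finite scores",
                                    call. = FALSE)
  if (is.unsorted(rev(scores))) stop("ranked list must be descending",
                                     call. = FALSE)
  invisible(scores)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: positions in the geneset ("hits") increment the
#' running sum by `|score|^weight_exp` normalized by the total hit weight;
#' misses decrement by `1 / (N - N_hits)`. The enrichment score is the
#' running-sum value of largest magnitude (signed).
#'
#' @param scores named numeric vector, descending (see [ranked_list()]).
#' @param geneset character vector; must intersect the ranked genes.
#' @param weight_exp weighting exponent (>= 0; 0 gives the classic
#'   unweighted KS statistic, default 1).
#' @return list: `es` and `running` (the full running sum).
#' @export
enrichment_score <- function(scores, geneset, weight_exp = 1) {
  check_ranked(scores)
  stopifnot(weight_exp >= 0)
  hit <- names(scores) %in% geneset
  if (!any(hit)) stop("geneset has no genes in the ranked list", call. = FALSE)
  N <- length(scores); Nh <- sum(hit)
  w <- abs(scores)^weight_exp
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / Nh, N)
  step <- ifelse(hit, inc, if (N > Nh) -1 / (N - Nh) else 0)
  running <- unname(cumsum(step))
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

# ES from sorted hit positions only (O(Nh)); used for permutation nulls.
# Extremes of the piecewise-linear walk occur at hit positions and just
# before each hit.
es_from_positions <- function(pos, w, N) {
  Nh <- length(pos)
  cw <- cumsum(w[pos])
  nr <- cw[Nh]
  miss <- if (N > Nh) 1 / (N - Nh) else 0
  if (nr == 0) { cw <- seq_len(Nh); nr <- Nh }
  at_hit <- cw / nr - (pos - seq_len(Nh)) * miss
  before <- c(0, at_hit[-Nh]) - (pos - c(1, pos[-Nh] + 1)) * miss
  cand <- unname(c(at_hit, before))
  cand[which.max(abs(cand))]
}

#' Permutation-normalised enrichment (NES) and p-value
#'
#' The null distribution is built from `n_perm` random genesets of the
#' same size drawn from the ranked genes (gene permutation, matching
#' preranked usage). NES = ES divided by the mean |null ES| of matching
#' sign; p = `(1 + #{|null| >= |ES|, matching sign}) / (1 + #matching)`.
#' Deterministic for a fixed seed.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param null_es optional precomputed null ES vector (shared across
#'   same-size genesets); when supplied, `n_perm` and `seed` are ignored.
#' @return list: `es`, `nes`, `p`, `n_more_extreme`, `n_perm`, `null_es`.
#' @export
nes_and_p <- function(scores, geneset, n_perm = 2000, seed = 1,
                      weight_exp = 1, null_es = NULL) {
  es <- enrichment_score(scores, geneset, weight_exp)$es
  N <- length(scores)
  Nh <- sum(names(scores) %in% geneset)
  if (is.null(null_es)) {
    stopifnot(n_perm >= 100)
    set.seed(seed)
    w <- abs(scores)^weight_exp
    null_es <- vapply(seq_len(n_perm), function(b) {
      es_from_positions(sort(sample.int(N, Nh)), w, N)
    }, numeric(1))
  }
  same <- null_es[sign(null_es) == sign(es)]
  if (!length(same)) {
    warning("no matching-sign null ES; p set to 1", call. = FALSE)
    nes <- NA_real_; n_extreme <- 0L; p <- 1
  } else {
    nes <- es / mean(abs(same))
    n_extreme <- sum(abs(same) >= abs(es))
    p <- (1 + n_extreme) / (1 + length(same))
  }
  list(es = es, nes = nes, p = p, n_more_extreme = n_extreme,
       n_perm = length(null_es), null_es = null_es)
}

#' Enrichment of genesets across cluster ranked lists
#'
#' Runs [nes_and_p()] for every (cluster, geneset) pair. Null ES
#' distributions are cached per (cluster, geneset size), so same-size
#' genesets share permutations within a cluster.
#'
#' @param ranked_lists named list of ranked score vectors, one per cluster.
#' @param genesets named list of character vectors; sets with no gene in a
#'   ranked list are skipped with a warning.
#' @param config an `scstate_config` supplying `n_perm`, `weight_exp`,
#'   `rng_seed`.
#' @return data.frame: cluster, geneset, es, nes, p, n_more_extreme,
#'   n_perm.
#' @export
enrich_clusters <- function(ranked_lists, genesets, config = default_config()) {
  rows <- list()
  for (cl in names(ranked_lists)) {
    scores <- ranked_lists[[cl]]
    cache <- new.env(parent = emptyenv())
    for (gs in names(genesets)) {
      size <- sum(names(scores) %in% genesets[[gs]])
      if (size == 0) {
        warning("geneset '", gs, "' has no genes in cluster ", cl,
                "'s ranked list; skipped", call. = FALSE)
        next
      }
      key <- as.character(size)
      null_es <- if (exists(key, cache)) get(key, cache) else NULL
      r <- nes_and_p(scores, genesets[[gs]], n_perm = config$n_perm,
                     seed = config$rng_seed, weight_exp = config$weight_exp,
                     null_es = null_es)
      assign(key, r$null_es, cache)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, geneset = gs, es = r$es, nes = r$nes, p = r$p,
        n_more_extreme = r$n_more_extreme, n_perm = r$n_perm,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Select the globally strongest genesets
#'
#' For each geneset takes the maximum |NES| across clusters and returns
#' the `n` largest (ties broken lexicographically by name).
#'
#' @param results data.frame from [enrich_clusters()].
#' @param n number of genesets (default 25).
#' @return character vector of geneset names.
#' @export
top_genesets <- function(results, n = 25) {
  stopifnot(nrow(results) > 0)
  agg <- tapply(abs(results$nes), results$geneset, max, na.rm = TRUE)
  agg <- agg[order(-agg, names(agg))]
  if (n > length(agg)) {
    warning("only ", length(agg), " genesets available (requested ", n, ")",
            call. = FALSE)
    n <- length(agg)
  }
  names(agg)[seq_len(n)]
}

#' Group clusters into superclusters by their NES profiles
#'
#' Hierarchical agglomerative clustering (average linkage, Euclidean
#' distance) of clusters in NES space over the selected genesets, cut into
#' `n_super` groups. Labels are letters; ordering follows increasing mean
#' NES over `proliferation_sets` when given, else the dendrogram order.
#'
#' @param results data.frame from [enrich_clusters()].
#' @param top_sets genesets spanning the NES space (see [top_genesets()]).
#' @param n_super number of superclusters (default 3).
#' @param proliferation_sets optional geneset names used to order labels.
#' @return list: `assignment` (named character vector cluster -> letter),
#'   `tree` (hclust), `nes_matrix` (clusters x genesets).
#' @export
assign_superclusters <- function(results, top_sets = unique(results$geneset),
                                 n_super = 3, proliferation_sets = NULL) {
  clusters <- unique(results$cluster)
  if (n_super > length(clusters)) {
    stop("n_super exceeds the number of clusters", call. = FALSE)
  }
  mat <- matrix(0, length(clusters), length(top_sets),
                dimnames = list(clusters, top_sets))
  sub <- results[results$geneset %in% top_sets, ]
  mat[cbind(sub$cluster, sub$geneset)] <- ifelse(is.na(sub$nes), 0, sub$nes)
  hc <- hclust(dist(mat), method = "average")
  groups <- cutree(hc, k = n_super)
  if (!is.null(proliferation_sets)) {
    prolif <- intersect(proliferation_sets, top_sets)
    score <- tapply(rowMeans(mat[, prolif, drop = FALSE]), groups, mean)
    ord <- order(score)
  } else {
    ord <- unique(groups[hc$order])
  }
  relabel <- setNames(LETTERS[seq_len(n_super)], ord)
  assignment <- relabel[as.character(groups)]
  names(assignment) <- clusters
  sc_log("enrich", length(clusters), " clusters -> ", n_super,
         " superclusters over ", length(top_sets), " genesets")
  list(assignment = assignment, tree = hc, nes_matrix = mat)
}

#' Supercluster-specific upregulated signatures
#'
#' Given per-contrast upregulated gene lists (`up_lists[[X]][[Y]]` = genes
#' up in supercluster X versus Y), supercluster X's signature is the
#' intersection of its up-lists over all its contrasts, minus every gene
#' appearing in any other supercluster's up-lists. Signatures are pairwise
#' disjoint by construction.
#'
#' @param up_lists nested named list of character vectors.
#' @return named list of character vectors, one per supercluster.
#' @export
supercluster_signatures <- function(up_lists) {
  out <- lapply(names(up_lists), function(x) {
    own <- Reduce(intersect, up_lists[[x]])
    others <- unlist(up_lists[setdiff(names(up_lists), x)], use.names = FALSE)
    sig <- setdiff(own, others)
    if (!length(sig)) warning("empty signature for supercluster ", x,
                              call. = FALSE)
    sig
  })
  names(out) <- names(up_lists)
  out
}
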