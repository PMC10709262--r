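# Marker detection between clusters: per-gene Welch t-tests for every
# ordered cluster pair, Holm correction across a gene's comparisons, the
# "some" combined p-value (k-th smallest Holm p, k = ceiling(min_prop * m)),
# Benjamini-Hochberg FDR across genes, and summary-logFC ranking.

#' Pairwise Welch t-tests between clusters
#'
#' For every ordered pair (target, other) and every gene: Welch
#' unequal-variance t statistic with Satterthwaite degrees of freedom and
#' two-sided p-value; logFC = mean(target) - mean(other) on the input
#' (log) scale. Genes with zero variance in both groups get p = 1 and
#' logFC = 0.
#'
#' @param expr genes x cells matrix (residuals or log-normalized values).
#' @param labels named cluster labels covering the columns of `expr`;
#'   every cluster must have at least 2 cells.
#' @param pooled use the pooled-variance (Student) test instead of Welch.
#' @return named list, one element per target cluster, each a list with
#'   matrices `p` and `lfc` (genes x other clusters).
#' @export
pairwise_tests <- function(expr, labels, pooled = FALSE) {
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop("labels must cover every column of expr", call. = FALSE)
  cl <- sort(unique(labels))
  n <- vapply(cl, function(g) sum(labels == g), integer(1))
  if (any(n < 2)) {
    stop("cluster(s) with fewer than 2 cells: ",
         paste(cl[n < 2], collapse = ", "),
         "; merge or exclude them before testing", call. = FALSE)
  }
  means <- vapply(cl, function(g) rowMeans(expr[, labels == g, drop = FALSE]),
                  numeric(nrow(expr)))
  vars <- vapply(cl, function(g) {
    sub <- expr[, labels == g, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2) / (ncol(sub) - 1)
  }, numeric(nrow(expr)))
  if (is.null(dim(means))) {                     # single-gene input
    means <- matrix(means, 1, dimnames = list(rownames(expr), cl))
    vars <- matrix(vars, 1, dimnames = list(rownames(expr), cl))
  }
  names(n) <- cl
  out <- lapply(seq_along(cl), function(a) {
    others <- setdiff(seq_along(cl), a)
    p <- lfc <- matrix(NA_real_, nrow(expr), length(others),
                       dimnames = list(rownames(expr), cl[others]))
    for (jj in seq_along(others)) {
      b <- others[jj]
      delta <- means[, a] - means[, b]
      if (pooled) {
        sp2 <- ((n[a] - 1) * vars[, a] + (n[b] - 1) * vars[, b]) /
          (n[a] + n[b] - 2)
        se2 <- sp2 * (1 / n[a] + 1 / n[b])
        df <- rep(n[a] + n[b] - 2, nrow(expr))
      } else {
        va <- vars[, a] / n[a]; vb <- vars[, b] / n[b]
        se2 <- va + vb
        df <- se2^2 / (va^2 / (n[a] - 1) + vb^2 / (n[b] - 1))
      }
      degen <- se2 == 0
      tstat <- ifelse(degen, 0, delta / sqrt(se2))
      pv <- ifelse(degen, 1, 2 * pt(-abs(tstat), ifelse(degen, 1, df)))
      p[, jj] <- pv
      lfc[, jj] <- ifelse(degen, 0, delta)
    }
    list(p = p, lfc = lfc)
  })
  names(out) <- cl
  sc_log("markers", length(cl), " clusters, ",
         length(cl) * (length(cl) - 1), " ordered pairs, ",
         nrow(expr), " genes")
  out
}

#' Holm step-down p-value adjustment
#'
#' `adj_(i) = max_(j <= i) min(1, (m - j + 1) * p_(j))` over the ascending
#' order statistics, restored to input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
holm_correct <- function(p) {
  m <- length(p)
  if (m == 0) return(p)
  o <- order(p)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  adj[order(o)]
}

#' Combined p-value over pairwise comparisons ("some" rule)
#'
#' With `m` Holm-corrected pairwise p-values per gene, the combined p is
#' the k-th smallest with `k = max(1, ceiling(min_prop * m))` — small iff
#' the gene is significant in at least a `min_prop` fraction of the
#' comparisons. `rule = "any"` takes the minimum (the literal
#' "minimum of the smallest 20%" reading); `rule = "all"` the maximum.
#'
#' @param holm_p matrix (genes x comparisons) of Holm-corrected p-values,
#'   or a vector for a single gene.
#' @param min_prop required fraction of comparisons, in (0, 1].
#' @param rule `"some"` (default), `"any"` or `"all"`.
#' @return list: `p` (combined p per gene) and `which` (index of the
#'   comparison attaining it, per gene).
#' @export
combine_some <- function(holm_p, min_prop = 0.2,
                         rule = c("some", "any", "all")) {
  rule <- match.arg(rule)
  if (is.null(dim(holm_p))) holm_p <- matrix(holm_p, nrow = 1)
  m <- ncol(holm_p)
  stopifnot(m >= 1, min_prop > 0, min_prop <= 1)
  k <- switch(rule,
              some = max(1, ceiling(min_prop * m)),
              any = 1L,
              all = m)
  res <- apply(holm_p, 1, function(row) {
    ord <- order(row)
    c(row[ord[k]], ord[k])
  })
  list(p = unname(res[1, ]), which = as.integer(res[2, ]))
}

#' Per-cluster marker tables
#'
#' Orchestrates the full marker chain for each cluster: pairwise tests,
#' per-gene Holm correction across the cluster's comparisons, the "some"
#' combined p, BH FDR across genes, and the summary logFC — the logFC of
#' the comparison whose Holm p equals the combined p (ties resolved
#' towards the largest |logFC|; `summary = "mean"` averages across
#' comparisons instead).
#'
#' @param expr genes x cells matrix.
#' @param labels named cluster labels.
#' @param config an `scstate_config` supplying `min_prop`.
#' @param rule combined-p rule, see [combine_some()].
#' @param summary `"representative"` (default) or `"mean"`.
#' @param pooled see [pairwise_tests()].
#' @return named list of data.frames (gene, combined_p, fdr, summary_lfc),
#'   one per cluster, ordered by decreasing summary_lfc; pairwise matrices
#'   attached as attribute `pairwise`.
#' @export
find_markers <- function(expr, labels, config = default_config(),
                         rule = "some", summary = c("representative", "mean"),
                         pooled = FALSE) {
  summary <- match.arg(summary)
  pw <- pairwise_tests(expr, labels, pooled = pooled)
  out <- lapply(names(pw), function(g) {
    p <- pw[[g]]$p; lfc <- pw[[g]]$lfc
    holm <- t(apply(p, 1, holm_correct))
    if (ncol(p) == 1) holm <- matrix(holm, ncol = 1)
    comb <- combine_some(holm, min_prop = config$min_prop, rule = rule)
    summary_lfc <- vapply(seq_len(nrow(p)), function(i) {
      if (summary == "mean") return(mean(lfc[i, ]))
      cand <- which(holm[i, ] == comb$p[i])
      if (!length(cand)) cand <- comb$which[i]
      lfc[i, cand[which.max(abs(lfc[i, cand]))]]
    }, numeric(1))
    df <- data.frame(gene = rownames(p), combined_p = comb$p,
                     fdr = p.adjust(comb$p, method = "BH"),
                     summary_lfc = summary_lfc, stringsAsFactors = FALSE)
    df[order(-df$summary_lfc), ]
  })
  names(out) <- names(pw)
  attr(out, "pairwise") <- pw
  out
}

#' Select top marker genes per cluster
#'
#' Keeps genes with FDR below `fdr_thr`, then returns the `top_n` by
#' summary logFC in the requested direction (descending for `up`,
#' ascending for `down`).
#'
#' @param marker_table one cluster's data.frame from [find_markers()].
#' @param fdr_thr FDR threshold (default 0.05).
#' @param top_n maximum genes to return (default 250); if fewer are
#'   available all are returned with a warning.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of genes (for `"both"`, a list with `up` and
#'   `down`).
#' @export
rank_and_select <- function(marker_table, fdr_thr = 0.05, top_n = 250,
                            direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (direction == "both") {
    return(list(up = rank_and_select(marker_table, fdr_thr, top_n, "up"),
                down = rank_and_select(marker_table, fdr_thr, top_n, "down")))
  }
  sig <- marker_table[marker_table$fdr < fdr_thr, ]
  if (direction == "up") {
    sig <- sig[sig$summary_lfc > 0, ]
    sig <- sig[order(-sig$summary_lfc), ]
  } else {
    sig <- sig[sig$summary_lfc < 0, ]
    sig <- sig[order(sig$summary_lfc), ]
  }
  if (nrow(sig) < top_n) {
    warning("only ", nrow(sig), " genes available (requested ", top_n, ")",
            call. = FALSE)
  }
  head(sig$gene, top_n)
}

#' Ranked list for preranked enrichment
#'
#' All genes of a cluster's marker table ordered by decreasing summary
#' logFC, as a named score vector (an RNK list).
#'
#' @param marker_table one cluster's data.frame from [find_markers()].
#' @return named numeric vector, descending.
#' @export
ranked_list <- function(marker_table) {
  ord <- order(-marker_table$summary_lfc)
  setNames(marker_table$summary_lfc[ord], marker_table$gene[ord])
}
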