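# Cell-cycle caller: five stage scores normalized within each cell,
# correlation-based assignment to expected stage profiles, iterative
# profile refinement, and a continuous circular phase from the first two
# principal components of the score vectors.

#' Default initial stage profiles
#'
#' One expected 5-score profile per stage: +1 at the stage's own position
#' and -0.25 elsewhere, standardized — "peaks at its own stage". The
#' refinement iteration replaces these with data-driven profiles, so the
#' exact initial values only seed the assignment.
#'
#' @return 5 x 5 numeric matrix, rows = profiles (in [CC_STAGES] order),
#'   columns = stage scores.
#' @export
default_stage_profiles <- function() {
  p <- matrix(-0.25, 5, 5, dimnames = list(CC_STAGES, CC_STAGES))
  diag(p) <- 1
  t(apply(p, 1, function(x) (x - mean(x)) / sd(x)))
}

#' Score each cell against the five stage genesets
#'
#' The raw score of a cell for a stage is its mean expression over that
#' stage's genes. The five raw scores are then normalized within each cell
#' (centred and divided by their sd across stages). Cells whose five raw
#' scores are all equal are flagged degenerate and left at zero.
#'
#' @param expr log-expression matrix (genes x cells).
#' @param stage_sets named list with one member per stage in [CC_STAGES];
#'   genes absent from `expr` are dropped with a warning, a stage with no
#'   matching genes is an error.
#' @return cells x 5 score matrix with attribute `degenerate` (logical
#'   per cell).
#' @export
score_stages <- function(expr, stage_sets) {
  missing_stage <- setdiff(CC_STAGES, names(stage_sets))
  if (length(missing_stage)) {
    stop("stage geneset(s) missing: ", paste(missing_stage, collapse = ", "),
         call. = FALSE)
  }
  raw <- sapply(CC_STAGES, function(s) {
    members <- stage_sets[[s]]
    present <- intersect(members, rownames(expr))
    if (!length(present)) {
      stop("no genes of stage set '", s, "' are present in the matrix",
           call. = FALSE)
    }
    if (length(present) < length(members)) {
      warning(length(members) - length(present), " gene(s) of stage '", s,
              "' absent from the matrix; dropped", call. = FALSE)
    }
    colMeans(expr[present, , drop = FALSE])
  })
  if (is.null(dim(raw))) {                       # single-cell input
    raw <- matrix(raw, nrow = 1, dimnames = list(colnames(expr), CC_STAGES))
  }
  mu <- rowMeans(raw)
  sdev <- apply(raw, 1, sd)
  degenerate <- sdev == 0
  scores <- (raw - mu) / ifelse(degenerate, 1, sdev)
  scores[degenerate, ] <- 0
  rownames(scores) <- colnames(expr)
  attr(scores, "degenerate") <- degenerate
  sc_log("cellcycle", "scored ", nrow(scores), " cells; ",
         sum(degenerate), " degenerate")
  scores
}

#' Assign cells to stages by profile correlation
#'
#' Each cell's 5-score vector is Pearson-correlated with each expected
#' stage profile; the cell is labelled with the best-correlated stage
#' (ties broken towards the earlier stage in cycle order). Cells whose
#' best correlation is below `cor_thr`, or whose score vector has zero
#' variance, are labelled `"unassigned"`.
#'
#' @param scores cells x 5 matrix from [score_stages()].
#' @param profiles 5 x 5 profile matrix (rows = stages).
#' @param cor_thr minimum correlation for a call (default 0.2).
#' @return data.frame: cell_id, stage, correlation.
#' @export
assign_stages <- function(scores, profiles = default_stage_profiles(),
                          cor_thr = 0.2) {
  stopifnot(ncol(scores) == 5, nrow(profiles) == 5)
  sds <- apply(scores, 1, sd)
  ok <- sds > 0
  cors <- matrix(NA_real_, nrow(scores), 5,
                 dimnames = list(rownames(scores), CC_STAGES))
  if (any(ok)) {
    # a zero-variance profile yields NA correlations; which.max skips NAs
    cors[ok, ] <- suppressWarnings(
      cor(t(scores[ok, , drop = FALSE]), t(profiles)))
  }
  best <- apply(cors, 1, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
  best_cor <- cors[cbind(seq_len(nrow(cors)),
                         ifelse(is.na(best), 1L, best))]
  best_cor[is.na(best)] <- NA_real_
  stage <- ifelse(is.na(best) | best_cor < cor_thr, "unassigned",
                  CC_STAGES[ifelse(is.na(best), 1L, best)])
  data.frame(cell_id = rownames(scores), stage = stage,
             correlation = best_cor, stringsAsFactors = FALSE)
}

#' Refine stage assignments by iterated profile re-estimation
#'
#' Starting from initial profiles, alternate: (1) re-estimate each stage's
#' profile as the mean score vector of its currently assigned cells (a
#' stage that loses all members keeps its previous profile); (2) reassign
#' all cells with [assign_stages()]. Stops at a label fixed point or after
#' `refine_iter` iterations.
#'
#' On data whose cell-cycle phases form a continuum (rather than discrete
#' blobs), the iteration has a neutrally stable rotational mode: once the
#' per-iteration label changes fall to the noise level, further iterations
#' slowly rotate all stage windows together, detaching the labels from the
#' geneset anchor without improving the partition. The `tol` convergence
#' tolerance therefore stops the loop when fewer than `tol * n_cells`
#' labels change in an iteration (default 1%); set `tol = 0` for strict
#' fixed-point semantics.
#'
#' @inheritParams assign_stages
#' @param init_profiles starting profiles.
#' @param refine_iter maximum iterations (>= 0; 0 reproduces
#'   [assign_stages()] with the initial profiles).
#' @param tol relative label-change tolerance for convergence (fraction of
#'   cells, default 0.01).
#' @return list: `assignment` (data.frame as in [assign_stages()]),
#'   `profiles` (final 5 x 5 matrix), `n_iter`, `converged`.
#' @export
refine_assignments <- function(scores, init_profiles = default_stage_profiles(),
                               cor_thr = 0.2, refine_iter = 200, tol = 0.01) {
  stopifnot(refine_iter >= 0, tol >= 0, tol < 1)
  max_changed <- max(0, floor(tol * nrow(scores)))
  profiles <- init_profiles
  assignment <- assign_stages(scores, profiles, cor_thr)
  n_iter <- 0L; converged <- FALSE
  while (n_iter < refine_iter) {
    for (s in CC_STAGES) {
      members <- assignment$stage == s
      if (any(members)) {
        profiles[s, ] <- colMeans(scores[members, , drop = FALSE])
      }
    }
    nxt <- assign_stages(scores, profiles, cor_thr)
    n_iter <- n_iter + 1L
    changed <- sum(nxt$stage != assignment$stage)
    sc_log("cellcycle", "refine iter ", n_iter, ": ", changed, " label changes")
    assignment <- nxt
    if (changed <= max_changed) { converged <- TRUE; break }
  }
  list(assignment = assignment, profiles = profiles,
       n_iter = n_iter, converged = converged)
}

#' Continuous circular cell-cycle phase
#'
#' Projects the 5-dimensional score vectors onto their first two principal
#' components and takes each cell's angle about the centroid. The raw
#' angle is then anchored: the plane is reflected if the circular mean
#' phases of the labelled stages run against cycle order, and rotated so
#' the mean phase of the anchor stage (G1.S, or the first labelled stage
#' present) sits at 0. Every cell receives a phase, including unassigned
#' ones.
#'
#' @param scores cells x 5 matrix from [score_stages()].
#' @param labels optional per-cell stage labels used for anchoring; by
#'   default computed with [refine_assignments()] at its defaults.
#' @return numeric vector of phases in `[0, 2*pi)`, named by cell.
#' @export
fit_circular_phase <- function(scores, labels = NULL) {
  degenerate <- attr(scores, "degenerate")
  if (is.null(degenerate)) degenerate <- apply(scores, 1, sd) == 0
  if (sum(!degenerate) < 3) {
    stop("need at least 3 non-degenerate cells for a circular fit", call. = FALSE)
  }
  if (is.null(labels)) labels <- refine_assignments(scores)$assignment$stage
  pr <- prcomp(scores, center = TRUE, scale. = FALSE)
  xy <- pr$x[, 1:2, drop = FALSE]
  theta <- atan2(xy[, 2], xy[, 1])

  winding <- function(th) {
    mu <- vapply(CC_STAGES, function(s) {
      m <- labels == s
      if (any(m)) circular_mean(th[m]) else NA_real_
    }, numeric(1))
    mu <- mu[!is.na(mu)]
    if (length(mu) < 3) return(list(k = 1, mu = mu))
    d <- diff(c(mu, mu[1])) %% (2 * pi)
    list(k = round(sum(d) / (2 * pi)), mu = mu)
  }
  fwd <- winding(theta)
  if (fwd$k != 1) {
    refl <- winding(-theta)
    if (refl$k == 1) { theta <- -theta; fwd <- refl }
  }
  anchor <- if ("G1.S" %in% names(fwd$mu)) fwd$mu[["G1.S"]]
            else if (length(fwd$mu)) fwd$mu[[1]] else 0
  out <- (theta - anchor) %% (2 * pi)
  names(out) <- rownames(scores)
  out
}

#' Run the full cell-cycle caller
#'
#' Convenience wrapper: [score_stages()], [refine_assignments()] and
#' [fit_circular_phase()] in sequence.
#'
#' @param expr log-expression matrix.
#' @param stage_sets stage genesets.
#' @param config an `scstate_config` supplying `cor_thr` and `refine_iter`.
#' @return data.frame: cell_id, the five stage scores, stage, correlation,
#'   theta; the final profiles are attached as attribute `profiles`.
#' @export
call_cell_cycle <- function(expr, stage_sets, config = default_config()) {
  scores <- score_stages(expr, stage_sets)
  ref <- refine_assignments(scores, cor_thr = config$cor_thr,
                            refine_iter = config$refine_iter)
  theta <- fit_circular_phase(scores, labels = ref$assignment$stage)
  out <- data.frame(cell_id = rownames(scores), scores,
                    stage = ref$assignment$stage,
                    correlation = ref$assignment$correlation,
                    theta = unname(theta),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "profiles") <- ref$profiles
  out
}

#' Collapse the five internal stages to four reporting labels
#'
#' Fixed mapping used for coarse summaries: M.G1 -> G1, G1.S -> G1/S,
#' S and G2 -> S/G2, G2.M -> G2/M; `"unassigned"` is passed through.
#'
#' @param stage character vector of five-stage labels.
#' @return character vector of four-group labels.
#' @export
stage_to_four <- function(stage) {
  map <- c(M.G1 = "G1", G1.S = "G1/S", S = "S/G2", G2 = "S/G2",
           G2.M = "G2/M", unassigned = "unassigned")
  unname(map[stage])
}
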