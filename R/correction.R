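# Removal of cell-cycle and library-complexity (PDG) signal from
# log-normalized expression by per-gene Gaussian least squares, the
# identity-link GLM default. Residuals feed the corrected clustering.

#' Build the covariate table for expression correction
#'
#' Default encoding is the continuous cell-cycle position, `(sin theta,
#' cos theta)`, plus PDG; a discrete encoding uses stage indicator columns
#' instead (first stage as reference). All columns are centred; columns
#' that are constant after centring are dropped with a warning.
#'
#' @param cc cell-cycle table with columns `cell_id`, `theta`, `stage`
#'   (as returned by [call_cell_cycle()]).
#' @param stats library statistics with columns `cell_id`, `pdg`.
#' @param encoding `"continuous"` (default) or `"stage"`.
#' @param extra optional numeric matrix/data.frame of additional
#'   covariates, rows aligned with `cc$cell_id`.
#' @return numeric matrix (cells x covariates) with cell rownames.
#' @export
build_covariates <- function(cc, stats, encoding = c("continuous", "stage"),
                             extra = NULL) {
  encoding <- match.arg(encoding)
  missing <- setdiff(cc$cell_id, stats$cell_id)
  if (length(missing)) {
    stop("library stats missing for cell(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  stats <- stats[match(cc$cell_id, stats$cell_id), ]
  if (encoding == "continuous") {
    X <- cbind(sin_theta = sin(cc$theta), cos_theta = cos(cc$theta),
               pdg = stats$pdg)
  } else {
    stages <- intersect(CC_STAGES, unique(cc$stage))
    dummies <- sapply(stages[-1], function(s) as.numeric(cc$stage == s))
    if (is.null(dim(dummies))) dummies <- matrix(dummies, ncol = length(stages) - 1)
    colnames(dummies) <- paste0("stage_", stages[-1])
    X <- cbind(dummies, pdg = stats$pdg)
  }
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  rownames(X) <- cc$cell_id
  X <- scale(X, center = TRUE, scale = FALSE)
  const <- apply(X, 2, function(v) max(abs(v)) < 1e-12)
  if (any(const)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  attr(X, "scaled:center") <- NULL
  X
}

#' Regress covariates out of an expression matrix
#'
#' For every gene, fits ordinary least squares of expression on an
#' intercept plus the covariate columns and returns the residuals. By
#' construction the residuals of each gene are orthogonal to every
#' covariate column.
#'
#' @param expr genes x cells matrix (log-normalized expression).
#' @param cov cells x covariates matrix from [build_covariates()].
#' @return genes x cells residual matrix with attribute
#'   `provenance = "residual"`.
#' @export
regress_out <- function(expr, cov) {
  stopifnot(ncol(expr) == nrow(cov))
  X <- cbind(intercept = 1, cov)
  if (ncol(expr) <= ncol(X)) {
    stop("need more cells than covariates (+ intercept)", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- t(qr.resid(qrX, t(expr)))
  dimnames(res) <- dimnames(expr)
  attr(res, "provenance") <- "residual"
  sc_log("correct", "regressed ", ncol(cov), " covariate(s) out of ",
         nrow(expr), " genes x ", ncol(expr), " cells")
  res
}
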