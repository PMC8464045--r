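#' Infer per-cell TF activities
#'
#' Maps surface-protein profiles through the trained interaction matrix:
#' \eqn{A = W P^T} (TFs x cells). Optionally z-scores each TF across cells
#' for display.
#'
#' @param model an `affinity_model` (or a bare TFs x proteins matrix).
#' @param P cells x proteins matrix with the model's proteins.
#' @param zscore z-score each TF row across cells?
#' @return TFs x cells activity matrix with attributes `kind =
#'   "tf_activity"` and `zscored`.
#' @export
infer_tf_activity <- function(model, P, zscore = FALSE) {
  W <- if (inherits(model, "affinity_model")) model$W else as.matrix(model)
  P <- as.matrix(P)
  if (!is.null(colnames(P)) && !is.null(colnames(W)) &&
      !identical(colnames(P), colnames(W))) {
    bad <- union(setdiff(colnames(P), colnames(W)),
                 setdiff(colnames(W), colnames(P)))
    if (length(bad)) stop("protein-id mismatch: ", paste(bad, collapse = ", "))
    P <- P[, colnames(W), drop = FALSE]
  }
  stopifnot(ncol(P) == ncol(W))
  A <- W %*% t(P)
  if (zscore) {
    mu <- rowMeans(A)
    sdv <- apply(A, 1, sd)
    sdv[sdv == 0] <- 1
    A <- (A - mu) / sdv
  }
  attr(A, "kind") <- "tf_activity"
  attr(A, "zscored") <- zscore
  A
}

#' Infer projected surface-protein activities
#'
#' Maps expression profiles through the model from the gene side:
#' \eqn{A = Y^T D W} (cells x proteins).
#'
#' @param Y genes x cells expression matrix.
#' @param D genes x TFs prior matrix.
#' @param model an `affinity_model` (or a bare TFs x proteins matrix).
#' @return Cells x proteins activity matrix with `kind =
#'   "protein_activity"`.
#' @export
infer_protein_activity <- function(Y, D, model) {
  W <- if (inherits(model, "affinity_model")) model$W else as.matrix(model)
  Y <- as.matrix(Y); D <- as.matrix(D)
  stopifnot(nrow(Y) == nrow(D), ncol(D) == nrow(W))
  A <- crossprod(Y, D) %*% W
  attr(A, "kind") <- "protein_activity"
  A
}

#' Permutation-based empirical null for TF activities
#'
#' For each of `n_perm` permutations the gene labels (rows) of Y are
#' shuffled — breaking the correspondence between expression and the
#' regulon prior D while preserving each cell's expression distribution —
#' the model is retrained with the same hyperparameters on the permuted
#' response, and the null TF activities \eqn{W_r P^T} are recorded.
#' \eqn{Y^T Y} is invariant under gene permutation and the SVD of P does
#' not change, so only \eqn{G = Y^T D} is recomputed per permutation.
#' `perm_axis = "cells"` permutes cell columns instead (diagnostic).
#'
#' @inheritParams build_reduced_system
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; the null is reproducible from it.
#' @param lambda1,lambda2 hyperparameters used for every refit (same as
#'   the observed fit).
#' @param perm_axis `"genes"` (default) or `"cells"`.
#' @return An object of class `null_model`: `samples` array (TFs x cells x
#'   n_perm), `n_perm`, `seed`, `perm_axis`.
#' @export
build_null_model <- function(Y, D, P, n_perm = 200, seed = 1,
                             lambda1 = 0, lambda2 = 1e-3,
                             var_retained = 1, perm_axis = c("genes", "cells")) {
  stopifnot(n_perm >= 1)
  perm_axis <- match.arg(perm_axis)
  Y <- as.matrix(Y); D <- as.matrix(D); P <- as.matrix(P)
  N <- nrow(Y); M <- ncol(Y)
  sys0 <- build_reduced_system(Y, D, P, var_retained)
  Q <- length(sys0$tf_ids)
  perms <- withr::with_seed(seed, lapply(seq_len(n_perm), function(r)
    sample.int(if (perm_axis == "genes") N else M)))
  samples <- array(NA_real_, dim = c(Q, M, n_perm),
                   dimnames = list(sys0$tf_ids, colnames(Y), NULL))
  for (r in seq_len(n_perm)) {
    sys_r <- sys0
    if (perm_axis == "genes") {
      Yp <- Y[perms[[r]], , drop = FALSE]
      sys_r$G <- crossprod(Yp, D)        # B = Y'Y unchanged
    } else {
      Yp <- Y[, perms[[r]], drop = FALSE]
      sys_r$G <- crossprod(Yp, D)
      sys_r$B <- crossprod(Yp)
    }
    fit <- tryCatch(
      if (lambda1 == 0) solve_ridge_reduced(sys_r, lambda2)
      else solve_elastic_net(sys_r, lambda1, lambda2),
      error = function(e) stop("permutation ", r, " failed: ",
                               conditionMessage(e)))
    samples[, , r] <- fit$W %*% t(P)
  }
  structure(list(samples = samples, n_perm = n_perm, seed = seed,
                 perm_axis = perm_axis, lambda1 = lambda1,
                 lambda2 = lambda2),
            class = "null_model")
}

#' Score TF-activity significance against the empirical null
#'
#' Two-tailed empirical p per (TF, cell): each tail probability is
#' \eqn{(b + 1)/(n_{perm} + 1)} with b the count of null samples at least
#' as extreme, and \eqn{p = \min(1, 2 \min(p_{lo}, p_{hi}))}. Bonferroni
#' correction multiplies by the number of TFs within each cell; BH q-values
#' across TFs within each cell are reported as an extra column. A TF's
#' frequency is the fraction of cells (optionally within each cell type)
#' where it passes the adjusted-p threshold.
#'
#' @param A observed TFs x cells activity matrix (same axes as the null).
#' @param null a `null_model`.
#' @param alpha adjusted-p significance threshold (default 0.15).
#' @param cell_types optional cell -> label vector for per-type
#'   frequencies.
#' @return An object of class `significance_report`: `table` tibble (tf,
#'   cell, activity, p, p_adj, q, direction, significant) and `frequency`
#'   tibble.
#' @export
score_significance <- function(A, null, alpha = 0.15, cell_types = NULL) {
  stopifnot(inherits(null, "null_model"))
  A <- as.matrix(A)
  dims <- dim(null$samples)
  stopifnot(nrow(A) == dims[1], ncol(A) == dims[2])
  Q <- nrow(A); M <- ncol(A); R <- null$n_perm
  if (Q * 2 / (R + 1) >= alpha)
    warning(sprintf(
      "minimum attainable Bonferroni-adjusted p (%.3g) >= alpha (%g): no call can be significant",
      Q * 2 / (R + 1), alpha))
  b_hi <- apply(null$samples >= rep(A, R), c(1, 2), sum) # broadcast over r
  b_lo <- apply(null$samples <= rep(A, R), c(1, 2), sum)
  p_hi <- (b_hi + 1) / (R + 1)
  p_lo <- (b_lo + 1) / (R + 1)
  p <- pmin(2 * pmin(p_hi, p_lo), 1)   # matrix first: pmin keeps dims
  p_adj <- pmin(Q * p, 1)
  q <- apply(p, 2, p.adjust, method = "BH")
  if (Q == 1) q <- matrix(q, nrow = 1)
  direction <- ifelse(p_hi <= p_lo, "high", "low")
  sig <- p_adj < alpha
  tfs <- rownames(A); if (is.null(tfs)) tfs <- paste0("TF", seq_len(Q))
  cells <- colnames(A); if (is.null(cells)) cells <- paste0("cell", seq_len(M))
  tab <- tibble::tibble(
    tf = rep(tfs, times = M),
    cell = rep(cells, each = Q),
    activity = as.vector(A),
    p = as.vector(p),
    p_adj = as.vector(p_adj),
    q = as.vector(q),
    direction = as.vector(direction),
    significant = as.vector(sig))
  if (is.null(cell_types)) {
    freq <- tibble::tibble(tf = tfs, frequency = rowMeans(sig))
  } else {
    lab <- cell_types[cells]
    groups <- split(seq_len(M), lab)
    freq <- do.call(rbind, lapply(names(groups), function(g)
      tibble::tibble(tf = tfs, cell_type = g,
                     frequency = rowMeans(sig[, groups[[g]], drop = FALSE]))))
  }
  structure(list(table = tab, frequency = freq, alpha = alpha,
                 n_perm = R),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf(
    "<significance_report> %d (TF, cell) tests | %d permutations | alpha=%g | %d significant\n",
    nrow(x$table), x$n_perm, x$alpha, sum(x$table$significant)))
  invisible(x)
}
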