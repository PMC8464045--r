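#' Build the Y-transpose-compressed system for affinity regression
#'
#' The bilinear model \eqn{D W P^T \approx Y} vectorizes to
#' \eqn{(P \otimes D)\,\mathrm{vec}(W) \approx \mathrm{vec}(Y)}; because
#' genes and cells are numerous, both sides are left-multiplied by
#' \eqn{Y^T}, giving the compact system
#' \eqn{(P \otimes Y^T D)\,\mathrm{vec}(W) \approx \mathrm{vec}(Y^T Y)}.
#' Optionally the protein matrix P is reduced by truncated SVD before
#' training; W is always reported back in original protein coordinates.
#'
#' @param Y genes x cells expression matrix.
#' @param D genes x TFs prior matrix.
#' @param P cells x proteins matrix.
#' @param var_retained fraction of squared singular value mass of P to
#'   retain (`1` keeps the full rank); `NULL` disables the SVD reduction
#'   entirely.
#' @return An object of class `reduced_system` with fields `G` (\eqn{Y^T D},
#'   cells x TFs), `B` (\eqn{Y^T Y}), `P_red`, `V_k`, `singular_values`,
#'   `svd_rank`, plus the id vectors.
#' @export
build_reduced_system <- function(Y, D, P, var_retained = 0.95) {
  stopifnot(nrow(Y) == nrow(D), ncol(Y) == nrow(P))
  Y <- as.matrix(Y); D <- as.matrix(D); P <- as.matrix(P)
  G <- crossprod(Y, D)                  # M x Q
  B <- crossprod(Y)                     # M x M
  if (is.null(var_retained)) {
    V_k <- diag(ncol(P))
    colnames(V_k) <- rownames(V_k) <- colnames(P)
    sys <- list(P_red = P, V_k = V_k, singular_values = svd(P)$d,
                svd_rank = NA_integer_)
  } else {
    stopifnot(var_retained > 0, var_retained <= 1)
    sv <- svd(P)
    pos <- sv$d > max(sv$d[1], 0) * 1e-12
    if (!any(pos)) stop("protein matrix has rank 0")
    cum <- cumsum(sv$d[pos]^2) / sum(sv$d[pos]^2)
    k <- which(cum >= var_retained - 1e-12)[1]
    sys <- list(P_red = P %*% sv$v[, seq_len(k), drop = FALSE],
                V_k = sv$v[, seq_len(k), drop = FALSE],
                singular_values = sv$d,
                svd_rank = k)
  }
  structure(c(list(G = G, B = B), sys,
              list(tf_ids = colnames(D), protein_ids = colnames(P),
                   cell_barcodes = colnames(Y))),
            class = "reduced_system")
}

.new_affinity_model <- function(W, sys, lambda1, lambda2,
                                converged = TRUE, iterations = 0L,
                                objective = NA_real_) {
  dimnames(W) <- list(sys$tf_ids, sys$protein_ids)
  structure(list(W = W, tf_ids = sys$tf_ids, protein_ids = sys$protein_ids,
                 lambda1 = lambda1, lambda2 = lambda2,
                 svd_rank = sys$svd_rank,
                 sparsity = mean(W == 0),
                 converged = converged, iterations = iterations,
                 objective = objective),
            class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf(
    "<affinity_model> %d TFs x %d proteins | lambda1=%g lambda2=%g | %.0f%% zeros\n",
    nrow(x$W), ncol(x$W), x$lambda1, x$lambda2, 100 * x$sparsity))
  invisible(x)
}

#' Closed-form ridge solution of the compressed system
#'
#' Solves \eqn{\min_W \|\mathrm{vec}(Y^T Y) - (P \otimes Y^T D)
#' \mathrm{vec}(W)\|_2^2 + \lambda_2 \|W\|_2^2} exactly via
#' eigendecompositions of the two Gram blocks (the Kronecker-structured
#' normal equations decouple). With SVD reduction the solve happens in
#' reduced coordinates and W is rotated back, which for the ridge penalty
#' is algebraically identical to solving against the rank-k reconstruction
#' of P.
#'
#' @param sys a `reduced_system`.
#' @param lambda2 ridge penalty (>= 0; 0 only if the system is nonsingular).
#' @return An `affinity_model`.
#' @export
solve_ridge_reduced <- function(sys, lambda2) {
  stopifnot(inherits(sys, "reduced_system"), lambda2 >= 0)
  C <- crossprod(sys$G)                        # Q x Q
  Rr <- crossprod(sys$P_red)                   # k x k
  Tr <- crossprod(sys$G, sys$B) %*% sys$P_red  # Q x k
  eC <- eigen(C, symmetric = TRUE)
  eR <- eigen(Rr, symmetric = TRUE)
  vC <- pmax(eC$values, 0)
  vR <- pmax(eR$values, 0)
  den <- outer(vC, vR) + lambda2
  if (any(den < 1e-14))
    stop("singular compressed system; use lambda2 > 0")
  Mm <- crossprod(eC$vectors, Tr) %*% eR$vectors
  # In exact arithmetic the numerator vanishes along numerically-zero
  # eigendirections (G u = 0 or P_red v = 0); zero it explicitly so tiny
  # lambda2 does not amplify floating-point residue there.
  zC <- vC <= max(vC) * 1e-10
  zR <- vR <= max(vR) * 1e-10
  Mm[zC, ] <- 0
  Mm[, zR] <- 0
  W_red <- eC$vectors %*% (Mm / den) %*% t(eR$vectors)
  W <- W_red %*% t(sys$V_k)
  .new_affinity_model(W, sys, lambda1 = 0, lambda2 = lambda2)
}

#' Largest useful L1 penalty for the compressed elastic net
#'
#' For the objective \eqn{\|b - A x\|^2 + \lambda_2\|x\|^2 +
#' \lambda_1\|x\|_1} with \eqn{A = P \otimes Y^T D}, the all-zero solution
#' is optimal exactly when \eqn{\lambda_1 \ge 2\|A^T b\|_\infty}.
#'
#' @param sys a `reduced_system`.
#' @return The kill-level scalar.
#' @export
lambda_max <- function(sys) {
  P_t <- sys$P_red %*% t(sys$V_k)
  2 * max(abs(crossprod(sys$G, sys$B) %*% P_t))
}

#' Elastic-net solution of the compressed system by coordinate descent
#'
#' Minimizes \eqn{\|\mathrm{vec}(Y^T Y) - (\tilde P \otimes Y^T D)
#' \mathrm{vec}(W)\|_2^2 + \lambda_2\|W\|_2^2 + \lambda_1\|W\|_1} where
#' \eqn{\tilde P} is the rank-k SVD reconstruction of P (equal to P when
#' `var_retained = 1`). The L1 penalty is applied to W in original protein
#' coordinates, so the full-rank reduction path is exactly equivalent to no
#' reduction. Cyclic coordinate descent with precomputed Gram blocks;
#' deterministic.
#'
#' @param sys a `reduced_system`.
#' @param lambda1 L1 penalty (>= 0).
#' @param lambda2 ridge penalty (>= 0).
#' @param tol convergence tolerance: iteration stops when the largest
#'   coefficient update in a sweep falls below `tol * (1 + max|W|)` (the
#'   objective is convex and non-increasing across sweeps).
#' @param max_iter maximum number of full sweeps.
#' @return An `affinity_model` (fields `converged`, `iterations`,
#'   `objective` report solver state).
#' @export
solve_elastic_net <- function(sys, lambda1, lambda2, tol = 1e-8,
                              max_iter = 10000) {
  stopifnot(inherits(sys, "reduced_system"), lambda1 >= 0, lambda2 >= 0)
  P_t <- sys$P_red %*% t(sys$V_k)              # M x S rank-k approx of P
  C <- crossprod(sys$G)                        # Q x Q
  R <- crossprod(P_t)                          # S x S
  Tm <- crossprod(sys$G, sys$B) %*% P_t        # Q x S
  Q <- nrow(Tm); S <- ncol(Tm)
  dC <- diag(C); dR <- diag(R)
  den <- outer(dC, dR) + lambda2
  if (any(den <= 0)) stop("zero-curvature coordinate; use lambda2 > 0")
  # warm start from the closed-form ridge solution (deterministic)
  W <- tryCatch(unname(solve_ridge_reduced(sys, max(lambda2, 1e-12))$W),
                error = function(e) matrix(0, Q, S))
  const <- sum(sys$B^2)
  objective <- function() {
    Fm <- C %*% W %*% R
    const - 2 * sum(Tm * W) + sum(W * Fm) +
      lambda2 * sum(W^2) + lambda1 * sum(abs(W))
  }
  res <- .cd_elastic_net(C, R, Tm, den, W, lambda1, tol,
                         as.integer(max_iter))
  W <- res$W
  if (!res$converged)
    warning("coordinate descent did not converge in ", max_iter, " sweeps")
  .new_affinity_model(W, sys, lambda1, lambda2, res$converged,
                      res$iterations, objective())
}

#' Fit the affinity-regression model
#'
#' Convenience wrapper: builds the compressed system and dispatches to the
#' closed-form ridge (`lambda1 = 0`) or the coordinate-descent elastic net.
#'
#' @inheritParams build_reduced_system
#' @inheritParams solve_elastic_net
#' @return An `affinity_model`.
#' @export
fit_affinity <- function(Y, D, P, lambda1 = 0, lambda2 = 1e-3,
                         var_retained = 0.95, tol = 1e-8,
                         max_iter = 10000) {
  sys <- build_reduced_system(Y, D, P, var_retained)
  if (lambda1 == 0) solve_ridge_reduced(sys, lambda2)
  else solve_elastic_net(sys, lambda1, lambda2, tol, max_iter)
}

#' Predict expression for new cells
#'
#' Applies the bilinear model to held-out protein profiles:
#' \eqn{\hat Y = D W P_{new}^T}. No renormalization is applied.
#'
#' @param model an `affinity_model`.
#' @param D genes x TFs prior matrix aligned with the model's TFs.
#' @param P_new cells x proteins matrix with the model's proteins.
#' @return Genes x cells predicted expression matrix.
#' @export
predict_expression <- function(model, D, P_new) {
  stopifnot(inherits(model, "affinity_model"))
  D <- as.matrix(D); P_new <- as.matrix(P_new)
  if (!is.null(colnames(D))) {
    if (!identical(colnames(D), model$tf_ids)) {
      bad <- union(setdiff(colnames(D), model$tf_ids),
                   setdiff(model$tf_ids, colnames(D)))
      if (length(bad)) stop("TF-id mismatch: ", paste(bad, collapse = ", "))
      D <- D[, model$tf_ids, drop = FALSE]
    }
  }
  if (!is.null(colnames(P_new))) {
    if (!identical(colnames(P_new), model$protein_ids)) {
      bad <- union(setdiff(colnames(P_new), model$protein_ids),
                   setdiff(model$protein_ids, colnames(P_new)))
      if (length(bad))
        stop("protein-id mismatch: ", paste(bad, collapse = ", "))
      P_new <- P_new[, model$protein_ids, drop = FALSE]
    }
  }
  stopifnot(ncol(D) == nrow(model$W), ncol(P_new) == ncol(model$W))
  D %*% model$W %*% t(P_new)
}

#' Cross-validate the regularization path
#'
#' Cells are partitioned into folds by a seeded shuffle; for every
#' (lambda1, lambda2) grid point and fold the model is trained on in-fold
#' cells and scored by the mean per-cell Spearman correlation between
#' predicted and measured expression of the held-out cells. Ties are broken
#' toward larger lambda1, then larger lambda2 (the sparser / smoother
#' model).
#'
#' @inheritParams build_reduced_system
#' @param grid data.frame with columns `lambda1`, `lambda2`.
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @return An object of class `cv_result`: `grid` scores tibble, `best`
#'   row, `folds`, `seed`, `fold_assignment`.
#' @export
cross_validate <- function(Y, D, P, grid = default_lambda_grid(),
                           folds = 5, seed = 1, var_retained = 0.95) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  M <- ncol(Y)
  stopifnot(M >= folds)
  fold_id <- withr::with_seed(seed,
    sample(rep(seq_len(folds), length.out = M)))
  scores <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    sys <- build_reduced_system(Y[, tr, drop = FALSE], D,
                                P[tr, , drop = FALSE], var_retained)
    for (i in seq_len(nrow(grid))) {
      model <- if (grid$lambda1[i] == 0)
        solve_ridge_reduced(sys, grid$lambda2[i])
      else solve_elastic_net(sys, grid$lambda1[i], grid$lambda2[i])
      Yhat <- as.matrix(D) %*% model$W %*% t(P[!tr, , drop = FALSE])
      rho <- spearman_per_cell(Yhat, Y[, !tr, drop = FALSE])$rho
      scores[i, f] <- mean(rho, na.rm = TRUE)
    }
  }
  mean_score <- rowMeans(scores)
  ord <- order(-mean_score, -grid$lambda1, -grid$lambda2)
  best <- ord[1]
  out <- tibble::tibble(lambda1 = grid$lambda1, lambda2 = grid$lambda2,
                        mean_score = mean_score)
  for (f in seq_len(folds)) out[[paste0("fold", f)]] <- scores[, f]
  structure(list(grid = out,
                 best = list(lambda1 = grid$lambda1[best],
                             lambda2 = grid$lambda2[best],
                             mean_score = mean_score[best]),
                 folds = folds, seed = seed, fold_assignment = fold_id),
            class = "cv_result")
}

#' Default log-spaced hyperparameter grid
#'
#' @param n points per axis (default 5, spanning 1e-4 ... 1).
#' @return data.frame with `lambda1`, `lambda2` columns (n^2 rows).
#' @export
default_lambda_grid <- function(n = 5) {
  lam <- 10^seq(-4, 0, length.out = n)
  expand.grid(lambda1 = lam, lambda2 = lam, KEEP.OUT.ATTRS = FALSE)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d-fold CV over %d grid points | best lambda1=%g lambda2=%g (mean rho %.3f)\n",
    x$folds, nrow(x$grid), x$best$lambda1, x$best$lambda2,
    x$best$mean_score))
  invisible(x)
}
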