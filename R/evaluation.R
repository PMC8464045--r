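#' Per-cell Spearman correlation between predicted and measured expression
#'
#' One rho per cell (column), with average-rank tie handling. Columns with
#' zero variance in either matrix yield `NA` and are excluded from
#' downstream means; the count of such cells is recorded.
#'
#' @param Y_pred,Y_true genes x cells matrices with identical ordering.
#' @param method_tag optional label stored alongside the scores.
#' @return Tibble (cell, rho, method); `attr(,"n_dropped")` counts NA rhos.
#' @export
spearman_per_cell <- function(Y_pred, Y_true, method_tag = NA_character_) {
  Y_pred <- as.matrix(Y_pred); Y_true <- as.matrix(Y_true)
  stopifnot(identical(dim(Y_pred), dim(Y_true)))
  M <- ncol(Y_true)
  rho <- vapply(seq_len(M), function(j) {
    a <- Y_pred[, j]; b <- Y_true[, j]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = "spearman")
  }, numeric(1))
  cells <- colnames(Y_true)
  if (is.null(cells)) cells <- paste0("cell", seq_len(M))
  out <- tibble::tibble(cell = cells, rho = rho, method = method_tag)
  attr(out, "n_dropped") <- sum(is.na(rho))
  out
}

#' Nearest-neighbour expression baseline
#'
#' For each test cell, find the training cell with the smallest Euclidean
#' distance in surface-protein space and copy its expression profile. Ties
#' are broken toward the lowest training-cell index.
#'
#' @param P_train training cells x proteins matrix.
#' @param Y_train genes x training-cells expression matrix.
#' @param P_test test cells x proteins matrix.
#' @return Genes x test-cells predicted expression matrix;
#'   `attr(,"neighbor")` holds the chosen training index per test cell.
#' @export
nearest_neighbor_baseline <- function(P_train, Y_train, P_test) {
  P_train <- as.matrix(P_train); P_test <- as.matrix(P_test)
  Y_train <- as.matrix(Y_train)
  stopifnot(nrow(P_train) >= 1, ncol(P_train) == ncol(P_test),
            ncol(Y_train) == nrow(P_train))
  # squared distances via the Gram expansion; which.min takes first minimum
  d2 <- outer(rowSums(P_test^2), rowSums(P_train^2), "+") -
    2 * tcrossprod(P_test, P_train)
  nn <- apply(d2, 1, which.min)
  out <- Y_train[, nn, drop = FALSE]
  colnames(out) <- rownames(P_test)
  attr(out, "neighbor") <- nn
  out
}

#' Compare two methods' per-cell scores (one-sided Wilcoxon signed-rank)
#'
#' Tests whether method a scores higher than method b on paired per-cell
#' correlations. Zero differences are dropped (Wilcoxon convention); the
#' exact distribution is used for n <= 25 pairs, otherwise the normal
#' approximation with continuity correction.
#'
#' @param scores_a,scores_b tibbles from [spearman_per_cell()] (paired by
#'   `cell`).
#' @return List with `statistic`, `p_value`, `n_pairs`.
#' @export
compare_methods <- function(scores_a, scores_b) {
  m <- merge(scores_a[, c("cell", "rho")], scores_b[, c("cell", "rho")],
             by = "cell", suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 6) stop("need >= 6 paired cells")
  d <- m$rho_a - m$rho_b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero")
    return(list(statistic = NA_real_, p_value = 1, n_pairs = 0L))
  }
  n_eff <- length(d)
  r <- rank(abs(d))                     # average ranks under ties
  V <- sum(r[d > 0])
  if (n_eff <= 25) {
    p <- .exact_signed_rank_upper(r, V)
  } else {
    # normal approximation with continuity correction (tie-corrected var)
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4
    z <- (V - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(statistic = V, p_value = p, n_pairs = n_eff)
}

# Exact upper-tail P(V >= v) of the signed-rank statistic under random
# sign flips, by dynamic programming over doubled ranks (integers even
# with average-rank ties).
.exact_signed_rank_upper <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1)          # counts[s + 1] = #assignments
  counts[1] <- 1
  for (w in r2) {
    shifted <- c(numeric(w), counts[seq_len(total + 1 - w)])
    counts <- counts + shifted
  }
  sum(counts[seq(as.integer(round(2 * v)) + 1, total + 1)]) / 2^length(r2)
}

#' Cross-validated model-vs-baseline comparison
#'
#' Runs the full evaluation protocol: seeded fold assignment, per-fold
#' training of the affinity model and of the nearest-neighbour baseline on
#' the same split, per-cell Spearman scoring of held-out cells.
#'
#' @inheritParams build_reduced_system
#' @param lambda1,lambda2 hyperparameters for the model fit in each fold.
#' @param folds number of folds.
#' @param seed fold-assignment seed.
#' @return An object of class `method_comparison`: `scores` tibble (cell,
#'   fold, method, rho) and `test` (the Wilcoxon comparison).
#' @export
evaluate_methods_cv <- function(Y, D, P, lambda1 = 0, lambda2 = 1e-3,
                                folds = 5, seed = 1, var_retained = 0.95) {
  M <- ncol(Y)
  stopifnot(M >= folds)
  fold_id <- withr::with_seed(seed,
    sample(rep(seq_len(folds), length.out = M)))
  res <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    model <- fit_affinity(Y[, tr, drop = FALSE], D, P[tr, , drop = FALSE],
                          lambda1, lambda2, var_retained)
    Yhat <- predict_expression(model, D, P[!tr, , drop = FALSE])
    Ynn <- nearest_neighbor_baseline(P[tr, , drop = FALSE],
                                     Y[, tr, drop = FALSE],
                                     P[!tr, , drop = FALSE])
    sa <- spearman_per_cell(Yhat, Y[, !tr, drop = FALSE], "affinity")
    sb <- spearman_per_cell(Ynn, Y[, !tr, drop = FALSE], "nearest_neighbor")
    sa$fold <- f; sb$fold <- f
    res[[f]] <- rbind(sa, sb)
  }
  scores <- do.call(rbind, res)
  test <- compare_methods(scores[scores$method == "affinity", ],
                          scores[scores$method == "nearest_neighbor", ])
  structure(list(scores = scores, test = test, folds = folds, seed = seed),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  mu <- tapply(x$scores$rho, x$scores$method, mean, na.rm = TRUE)
  cat(sprintf(
    "<method_comparison> mean rho: affinity %.3f vs nearest-neighbor %.3f | one-sided Wilcoxon p = %.3g\n",
    mu[["affinity"]], mu[["nearest_neighbor"]], x$test$p_value))
  invisible(x)
}
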