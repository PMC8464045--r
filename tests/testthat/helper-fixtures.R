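# Shared fixtures and independent oracles, built in code at test time.

# random well-conditioned instance for solver checks
rand_instance <- function(N, M, Q, S, seed) {
  withr::with_seed(seed, {
    Y <- matrix(rnorm(N * M), N, M,
                dimnames = list(sprintf("g%03d", 1:N), sprintf("c%03d", 1:M)))
    D <- matrix(rbinom(N * Q, 1, 0.3), N, Q,
                dimnames = list(rownames(Y), sprintf("TF%02d", 1:Q)))
    for (j in which(colSums(D) == 0)) D[sample.int(N, 1), j] <- 1
    P <- matrix(rnorm(M * S), M, S,
                dimnames = list(colnames(Y), sprintf("ADT%02d", 1:S)))
    list(Y = Y, D = D, P = P)
  })
}

# brute-force oracle: explicit Kronecker ridge solve of the compressed system
kron_ridge_oracle <- function(Y, D, P, lambda2) {
  G <- crossprod(Y, D)
  A <- kronecker(P, G)
  b <- as.vector(crossprod(Y))
  x <- solve(crossprod(A) + lambda2 * diag(ncol(A)), crossprod(A, b))
  matrix(x, ncol(D), ncol(P))
}

# explicit elastic-net objective on the compressed system
compressed_objective <- function(W, Y, D, P, lambda1, lambda2) {
  G <- crossprod(Y, D)
  resid <- crossprod(Y) - G %*% W %*% t(P)
  sum(resid^2) + lambda2 * sum(W^2) + lambda1 * sum(abs(W))
}

# two planted protein blobs differing in the first `nplant` proteins
planted_blobs <- function(M = 30, S = 40, nplant = 3, shift = 4, seed = 13) {
  withr::with_seed(seed, {
    P <- matrix(rnorm(M * S), M, S,
                dimnames = list(sprintf("c%03d", 1:M), sprintf("ADT%02d", 1:S)))
    P[seq_len(M / 2), seq_len(nplant)] <-
      P[seq_len(M / 2), seq_len(nplant)] + shift
    P
  })
}

# counts object with a prescribed number of expressed genes per cell
counts_with_gene_profile <- function(genes_per_cell, n_genes = NULL) {
  if (is.null(n_genes)) n_genes <- max(genes_per_cell)
  n_cells <- length(genes_per_cell)
  i <- unlist(lapply(genes_per_cell, seq_len))
  j <- rep(seq_len(n_cells), genes_per_cell)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n_genes, n_cells))
  raw_counts(m, sprintf("g%05d", seq_len(n_genes)),
             sprintf("cell%02d", seq_len(n_cells)), "rna")
}
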