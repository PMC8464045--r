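#' Configuration for the synthetic CITE-seq generator
#'
#' @param n_genes,n_cells,n_tfs,n_proteins dimensions (>= 1).
#' @param prior_density Bernoulli density of the binary regulon matrix D.
#' @param w_sparsity fraction of planted interaction weights zeroed.
#' @param noise_sd Gaussian noise SD added to the clean expression
#'   (exactly one of `noise_sd`/`snr` must be given).
#' @param snr signal-to-noise ratio: expected
#'   \eqn{\|Y_{clean}\|_F^2 / \|noise\|_F^2}.
#' @param count_depth UMI depth per cell for the raw-count emulation.
#' @param adt_depth expected ADT depth per cell (default count_depth / 10).
#' @param seed integer seed; all outputs are a pure function of the
#'   config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes, n_cells, n_tfs, n_proteins,
                       prior_density = 0.1, w_sparsity = 0,
                       noise_sd = NULL, snr = NULL,
                       count_depth = 5000, adt_depth = count_depth / 10,
                       seed = 1) {
  stopifnot(n_genes >= 1, n_cells >= 1, n_tfs >= 1, n_proteins >= 1,
            prior_density > 0, prior_density <= 1,
            w_sparsity >= 0, w_sparsity < 1)
  if (is.null(noise_sd) == is.null(snr))
    stop("set exactly one of noise_sd or snr")
  structure(list(n_genes = n_genes, n_cells = n_cells, n_tfs = n_tfs,
                 n_proteins = n_proteins, prior_density = prior_density,
                 w_sparsity = w_sparsity, noise_sd = noise_sd, snr = snr,
                 count_depth = count_depth, adt_depth = adt_depth,
                 seed = seed),
            class = "sim_config")
}

.sim_ids <- function(cfg) {
  list(genes = sprintf("g%03d", seq_len(cfg$n_genes)),
       cells = sprintf("cell%04d", seq_len(cfg$n_cells)),
       tfs = sprintf("TF%02d", seq_len(cfg$n_tfs)),
       proteins = sprintf("ADT%02d", seq_len(cfg$n_proteins)))
}

.sim_prior <- function(cfg, ids) {
  D <- matrix(rbinom(cfg$n_genes * cfg$n_tfs, 1, cfg$prior_density),
              cfg$n_genes, cfg$n_tfs, dimnames = list(ids$genes, ids$tfs))
  empty <- colSums(D) == 0
  for (j in which(empty)) D[sample.int(cfg$n_genes, 1), j] <- 1
  D
}

.sim_counts <- function(cfg, ids, Y, P_lat) {
  # RNA: multinomial per cell, probabilities = softmax of the cell's
  # z-scored expression column (keeps the dynamic range sample-able so the
  # normalization round-trip preserves ranks)
  Z <- scale(Y)
  Z[is.nan(Z)] <- 0
  rna <- vapply(seq_len(cfg$n_cells), function(j) {
    pr <- exp(Z[, j] - max(Z[, j]))
    rmultinom(1, cfg$count_depth, pr / sum(pr))[, 1]
  }, numeric(cfg$n_genes))
  dimnames(rna) <- list(ids$genes, ids$cells)
  # ADT: Poisson around exp-scaled latent protein abundance
  lam <- exp(t(P_lat))                  # proteins x cells
  lam <- sweep(lam, 2, cfg$adt_depth / colSums(lam), "*")
  adt <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam),
                dimnames = list(ids$proteins, ids$cells))
  list(rna = raw_counts(rna, ids$genes, ids$cells, "rna"),
       adt = raw_counts(adt, ids$proteins, ids$cells, "adt"))
}

#' Generate a synthetic CITE-seq instance with planted bilinear structure
#'
#' Draws a sparse binary regulon matrix D, a planted interaction matrix
#' W*, non-negative latent protein abundances P, and expression
#' \eqn{Y = D W^* P^T + \varepsilon}. Raw counts emulating the measurement
#' process are produced by inverting the normalizations (multinomial UMI
#' sampling for RNA, Poisson for ADT), so the full I/O pipeline can be
#' exercised end to end without external data.
#'
#' @param cfg a [sim_config()].
#' @return List: `rna`, `adt` ([raw_counts]), `D`, `W_star`, `P_latent`,
#'   `Y_clean`, `Y` (observed), `noise_sd`.
#' @export
generate_instance <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    ids <- .sim_ids(cfg)
    D <- .sim_prior(cfg, ids)
    W <- matrix(rnorm(cfg$n_tfs * cfg$n_proteins), cfg$n_tfs,
                cfg$n_proteins, dimnames = list(ids$tfs, ids$proteins))
    if (cfg$w_sparsity > 0) {
      nz <- round(cfg$w_sparsity * length(W))
      W[sample.int(length(W), nz)] <- 0
    }
    P_lat <- matrix(abs(rnorm(cfg$n_cells * cfg$n_proteins)),
                    cfg$n_cells, cfg$n_proteins,
                    dimnames = list(ids$cells, ids$proteins))
    Y_clean <- D %*% W %*% t(P_lat)
    noise_sd <- if (!is.null(cfg$noise_sd)) cfg$noise_sd
      else sqrt(sum(Y_clean^2) / (cfg$snr * length(Y_clean)))
    Y <- Y_clean + matrix(rnorm(length(Y_clean), sd = noise_sd),
                          nrow(Y_clean), ncol(Y_clean))
    dimnames(Y) <- dimnames(Y_clean)
    counts <- .sim_counts(cfg, ids, Y, P_lat)
    list(rna = counts$rna, adt = counts$adt, D = D, W_star = W,
         P_latent = P_lat, Y_clean = Y_clean, Y = Y, noise_sd = noise_sd)
  })
}

#' Generate a null instance (expression independent of D and P)
#'
#' Same D and latent P as [generate_instance()] would draw, but Y is pure
#' Gaussian noise with no bilinear structure: used to calibrate the
#' permutation significance machinery and CV behaviour under the null.
#'
#' @param cfg a [sim_config()]; `noise_sd` sets the noise scale (with
#'   `snr` given, scale 1 is used).
#' @return Same shape as [generate_instance()], with `W_star` all zeros
#'   and `Y_clean` all zeros.
#' @export
generate_null_instance <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    ids <- .sim_ids(cfg)
    D <- .sim_prior(cfg, ids)
    W <- matrix(0, cfg$n_tfs, cfg$n_proteins,
                dimnames = list(ids$tfs, ids$proteins))
    P_lat <- matrix(abs(rnorm(cfg$n_cells * cfg$n_proteins)),
                    cfg$n_cells, cfg$n_proteins,
                    dimnames = list(ids$cells, ids$proteins))
    noise_sd <- if (!is.null(cfg$noise_sd)) cfg$noise_sd else 1
    Y <- matrix(rnorm(cfg$n_genes * cfg$n_cells, sd = noise_sd),
                cfg$n_genes, cfg$n_cells,
                dimnames = list(ids$genes, ids$cells))
    counts <- .sim_counts(cfg, ids, Y, P_lat)
    list(rna = counts$rna, adt = counts$adt, D = D, W_star = W,
         P_latent = P_lat,
         Y_clean = matrix(0, cfg$n_genes, cfg$n_cells,
                          dimnames = dimnames(Y)),
         Y = Y, noise_sd = noise_sd)
  })
}

#' Write a generated instance to disk as test fixtures
#'
#' MTX triplet directories for RNA and ADT counts, the prior edge list as
#' TSV, and the ground-truth W* and latent P as TSV.
#'
#' @param instance output of [generate_instance()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_instance <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_mtx(instance$rna, file.path(dir, "rna"))
  write_counts_mtx(instance$adt, file.path(dir, "adt"))
  edges <- which(instance$D == 1, arr.ind = TRUE)
  write.table(
    data.frame(tf = colnames(instance$D)[edges[, 2]],
               gene = rownames(instance$D)[edges[, 1]]),
    file.path(dir, "prior.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(instance$W_star, file.path(dir, "W_star.tsv"),
              sep = "\t", quote = FALSE)
  write.table(instance$P_latent, file.path(dir, "P_latent.tsv"),
              sep = "\t", quote = FALSE)
  invisible(dir)
}
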