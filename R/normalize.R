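#' Log-normalize RNA counts
#'
#' Per cell j with total UMI count \eqn{T_j}, each entry becomes
#' \eqn{\ln(1 + s\, c_{gj} / T_j)} with size factor \eqn{s} (default
#' 10,000 molecules per cell). Invariant to uniform rescaling of a cell's
#' counts.
#'
#' @param rna a [raw_counts] object (RNA modality).
#' @param size_factor pseudo-library size each cell is scaled to.
#' @return Dense genes x cells matrix; `attr(,"normalization") = "lognorm"`.
#' @export
log_normalize_rna <- function(rna, size_factor = 10000) {
  stopifnot(inherits(rna, "raw_counts"))
  totals <- Matrix::colSums(rna$matrix)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(rna$cell_barcodes[totals == 0], collapse = ", "),
         " (run qc_filter_cells first)")
  m <- as.matrix(rna$matrix)
  out <- log1p(sweep(m, 2, totals / size_factor, "/"))
  dimnames(out) <- list(rna$feature_ids, rna$cell_barcodes)
  attr(out, "normalization") <- "lognorm"
  out
}

#' Centered log-ratio normalization for ADT counts
#'
#' Default variant: \eqn{\mathrm{clr}_{ij} = \ln(1 + x_{ij}) -
#' \mathrm{mean}_{j'} \ln(1 + x_{ij'})}, centered per protein ACROSS CELLS,
#' so every protein's transformed mean over cells is exactly 0. The
#' `"seurat"` variant reproduces Seurat's log1p/geometric-mean formula
#' (which does not have the zero-mean property).
#'
#' @param adt a [raw_counts] object (ADT modality).
#' @param method `"center"` (default) or `"seurat"`.
#' @return Dense cells x proteins matrix (note the transpose relative to
#'   the input), `attr(,"normalization") = "clr"`.
#' @export
clr_normalize_adt <- function(adt, method = c("center", "seurat")) {
  stopifnot(inherits(adt, "raw_counts"))
  if (adt$modality != "adt") stop("clr_normalize_adt expects ADT counts")
  method <- match.arg(method)
  x <- as.matrix(adt$matrix)            # proteins x cells
  zero_prot <- Matrix::rowSums(x) == 0
  if (any(zero_prot))
    warning("all-zero protein(s): ",
            paste(adt$feature_ids[zero_prot], collapse = ", "))
  lx <- log1p(x)
  if (method == "center") {
    out <- lx - rowMeans(lx)
  } else {
    # Seurat CLR: log1p(x / exp(mean of log1p over the full margin))
    gm <- exp(rowMeans(lx))
    out <- log1p(x / gm)
  }
  out <- t(out)                          # cells x proteins
  dimnames(out) <- list(adt$cell_barcodes, adt$feature_ids)
  attr(out, "normalization") <- "clr"
  out
}

#' Build the binary TF-regulon prior matrix
#'
#' Turns a TF -> target edge list into a genes x TFs binary membership
#' matrix over a fixed gene universe. Edges pointing outside the universe
#' are dropped (count recorded), TFs absent from `expressed_tfs` are
#' removed, and TF columns left without any surviving target are removed.
#'
#' @param edges data.frame with columns `tf`, `gene` (duplicates allowed).
#' @param gene_universe character vector of genes defining the rows.
#' @param expressed_tfs TFs to retain; defaults to all TFs in `edges`.
#' @return Binary genes x TFs matrix; attributes `dropped_edges` (count)
#'   and `dropped_tfs` (names).
#' @export
build_prior_matrix <- function(edges, gene_universe,
                               expressed_tfs = unique(edges$tf)) {
  if (!nrow(edges)) stop("empty edge list")
  requested <- intersect(unique(edges$tf), expressed_tfs)
  in_univ <- edges$gene %in% gene_universe
  n_drop <- sum(!in_univ)
  edges <- edges[in_univ & edges$tf %in% expressed_tfs, , drop = FALSE]
  if (!nrow(edges)) stop("no edges survive gene-universe/TF filtering")
  tfs <- sort(unique(edges$tf))
  D <- matrix(0, length(gene_universe), length(tfs),
              dimnames = list(gene_universe, tfs))
  D[cbind(match(edges$gene, gene_universe), match(edges$tf, tfs))] <- 1
  empty <- colSums(D) == 0
  D <- D[, !empty, drop = FALSE]
  if (!ncol(D)) stop("no TF retains any target after filtering")
  attr(D, "dropped_edges") <- n_drop
  attr(D, "dropped_tfs") <- setdiff(requested, colnames(D))
  D
}

.unit_norm_cols <- function(m) {
  nrm <- sqrt(colSums(m^2))
  keep <- nrm > 0
  list(m = sweep(m[, keep, drop = FALSE], 2, nrm[keep], "/"),
       dropped = colnames(m)[!keep])
}

#' Align expression, protein and prior matrices and unit-normalize columns
#'
#' Restricts Y (genes x cells), P (cells x proteins) and D (genes x TFs) to
#' the common cells (Y, P) and common genes (Y, D), in identical order, then
#' divides every column of every matrix by its L2 norm. All-zero columns are
#' dropped with the dependent bookkeeping (a zero Y column drops the cell
#' from P too; zero TF/protein columns are dropped from D/P).
#'
#' @param Y genes x cells expression matrix.
#' @param P cells x proteins matrix.
#' @param D genes x TFs binary prior matrix.
#' @return List with elements `Y`, `P`, `D` and `dropped` (named list of
#'   dropped cells/proteins/tfs).
#' @export
align_and_unit_normalize <- function(Y, P, D) {
  cells <- intersect(colnames(Y), rownames(P))
  if (!length(cells)) stop("empty intersection on axis: cells (Y vs P)")
  genes <- intersect(rownames(Y), rownames(D))
  if (!length(genes)) stop("empty intersection on axis: genes (Y vs D)")
  Y <- Y[genes, cells, drop = FALSE]
  P <- P[cells, , drop = FALSE]
  D <- D[genes, , drop = FALSE]

  yn <- .unit_norm_cols(Y)
  dropped_cells <- yn$dropped
  Y <- yn$m
  if (length(dropped_cells))
    P <- P[setdiff(cells, dropped_cells), , drop = FALSE]
  pn <- .unit_norm_cols(P)
  dn <- .unit_norm_cols(D)
  list(Y = Y, P = pn$m, D = dn$m,
       dropped = list(cells = dropped_cells, proteins = pn$dropped,
                      tfs = dn$dropped))
}
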