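#' Pearson correlation between TF activities and protein expression
#'
#' One coefficient per (TF, protein) pair across the shared cells.
#' Zero-variance features yield `NA` (count recorded).
#'
#' @param A TFs x cells activity matrix.
#' @param P cells x proteins matrix (same cells, same order).
#' @return TFs x proteins correlation matrix; `attr(,"n_cells")`,
#'   `attr(,"n_na")`.
#' @export
tf_protein_correlation <- function(A, P) {
  A <- as.matrix(A); P <- as.matrix(P)
  stopifnot(ncol(A) == nrow(P))
  if (nrow(P) < 3) stop("need >= 3 shared cells")
  r <- suppressWarnings(cor(t(A), P))
  attr(r, "n_cells") <- nrow(P)
  attr(r, "n_na") <- sum(is.na(r))
  r
}

#' TF-protein pathway co-occurrence matrix
#'
#' Binary TFs x proteins matrix: 1 iff the TF and the protein (after
#' mapping ADT names to gene symbols through the alias table) share at
#' least one pathway.
#'
#' @param pathways named list of member symbol vectors (see [read_gmt()]).
#' @param tfs TF symbols (rows).
#' @param proteins ADT/protein names (columns).
#' @param alias optional data.frame (adt_name, gene_symbol) mapping ADT
#'   names to gene symbols for pathway lookup.
#' @return Binary TFs x proteins matrix.
#' @export
pathway_cooccurrence <- function(pathways, tfs, proteins, alias = NULL) {
  prot_sym <- proteins
  if (!is.null(alias)) {
    i <- match(proteins, alias[[1]])
    prot_sym[!is.na(i)] <- alias[[2]][i[!is.na(i)]]
  }
  membership <- function(sym)
    vapply(pathways, function(p) sym %in% p, logical(1))
  tf_mem <- vapply(tfs, membership, logical(length(pathways)))
  pr_mem <- vapply(prot_sym, membership, logical(length(pathways)))
  cooc <- (crossprod(tf_mem, pr_mem) > 0) * 1L
  dimnames(cooc) <- list(tfs, proteins)
  cooc
}

#' Pathway co-occurrence enrichment of correlated TF-protein pairs
#'
#' Pairs are called correlated when |r| > `r_hi` and uncorrelated when
#' |r| < `r_lo`; the intermediate band and NA pairs are excluded. A 2x2
#' contingency table (shares-a-pathway yes/no x correlated/uncorrelated)
#' is tested by the upper-tail hypergeometric probability of at least the
#' observed overlap (identical to Fisher's one-sided exact test).
#'
#' @param corr TFs x proteins Pearson correlation matrix.
#' @param cooc binary TFs x proteins co-occurrence matrix (same dims).
#' @param r_hi correlated threshold on |r| (default 0.4, exclusive).
#' @param r_lo uncorrelated threshold on |r| (default 0.2, exclusive).
#' @return List: `table` (2x2), `p_value`, `n_pairs_used`.
#' @export
enrichment_test <- function(corr, cooc, r_hi = 0.4, r_lo = 0.2) {
  stopifnot(identical(dim(corr), dim(cooc)))
  a <- abs(as.vector(corr))
  share <- as.vector(cooc) == 1
  keep <- !is.na(a) & (a > r_hi | a < r_lo)
  a <- a[keep]; share <- share[keep]
  correlated <- a > r_hi
  if (!any(correlated) || all(correlated))
    stop("degenerate correlation margin: ",
         if (!any(correlated)) "no correlated pairs" else "no uncorrelated pairs")
  tab <- rbind(shares = c(correlated = sum(share & correlated),
                          uncorrelated = sum(share & !correlated)),
               no_pathway = c(sum(!share & correlated),
                              sum(!share & !correlated)))
  k11 <- tab[1, 1]
  K <- sum(tab[1, ])       # pairs sharing a pathway
  N <- sum(tab)            # all classified pairs
  n <- sum(tab[, 1])       # correlated pairs
  p <- phyper(k11 - 1, K, N - K, n, lower.tail = FALSE)
  list(table = tab, p_value = p, n_pairs_used = N)
}

.canonical_cluster_ids <- function(assign, barcodes) {
  # relabel clusters by decreasing size, ties by smallest member barcode,
  # so the partition is invariant to cell input order
  sizes <- table(assign)
  firsts <- vapply(split(barcodes, assign),
                   function(b) min(b), character(1))
  ord <- order(-as.integer(sizes), firsts[names(sizes)])
  new_id <- setNames(seq_along(ord), names(sizes)[ord])
  unname(new_id[as.character(assign)])
}

#' Cluster cells by surface-protein expression with differential refinement
#'
#' Hierarchical clustering (Ward's D2 linkage on correlation distance
#' 1 - r between cells) is cut into `init_groups` groups; the cut is
#' accepted only if every cluster is separable from every other cluster by
#' at least `min_markers` differential proteins (two-sample Wilcoxon
#' rank-sum per protein between the pair of clusters, BH-FDR < `fdr`
#' across proteins). While any pair of clusters is indistinguishable, the
#' same dendrogram is re-cut with one fewer group, down to 2 groups.
#' Deterministic. The reported per-cluster differential table compares
#' each final cluster against all other cells.
#'
#' @param P cells x proteins matrix.
#' @param exclude protein names to drop before clustering (e.g. lineage
#'   markers).
#' @param init_groups initial number of groups (default 10).
#' @param fdr BH-FDR threshold for a differential protein (default 0.05).
#' @param min_markers required differential proteins per cluster
#'   (default 2).
#' @return An object of class `cluster_assignment`: `clusters` (named
#'   integer vector, barcode -> id), `diff_proteins` tibble (cluster,
#'   protein, effect, p, q), `k`, `iterations`, `all_qualified`.
#' @export
cluster_cells_by_protein <- function(P, exclude = NULL, init_groups = 10,
                                     fdr = 0.05, min_markers = 2) {
  P <- as.matrix(P)
  if (!is.null(exclude))
    P <- P[, setdiff(colnames(P), exclude), drop = FALSE]
  M <- nrow(P)
  stopifnot(M >= init_groups)
  barcodes <- rownames(P)
  if (is.null(barcodes)) barcodes <- paste0("cell", seq_len(M))
  cr <- suppressWarnings(cor(t(P)))
  cr[is.na(cr)] <- 0
  hc <- hclust(as.dist(1 - cr), method = "ward.D2")

  diff_for <- function(assign, k) {
    do.call(rbind, lapply(seq_len(k), function(cl) {
      inside <- assign == cl
      res <- lapply(colnames(P), function(prot) {
        xi <- P[inside, prot]; xo <- P[!inside, prot]
        if (length(unique(c(xi, xo))) == 1L)
          return(c(effect = 0, p = 1))
        p <- suppressWarnings(
          wilcox.test(xi, xo, exact = FALSE)$p.value)
        c(effect = mean(xi) - mean(xo), p = p)
      })
      res <- do.call(rbind, res)
      tibble::tibble(cluster = cl, protein = colnames(P),
                     effect = res[, "effect"], p = res[, "p"],
                     q = p.adjust(res[, "p"], "BH"))
    }))
  }

  # a pair of clusters is separable if >= min_markers proteins differ at
  # BH-FDR < fdr in a pairwise rank-sum test
  pair_separable <- function(i1, i2) {
    pv <- vapply(colnames(P), function(prot) {
      xi <- P[i1, prot]; xo <- P[i2, prot]
      if (length(unique(c(xi, xo))) == 1L) return(1)
      suppressWarnings(wilcox.test(xi, xo, exact = FALSE)$p.value)
    }, numeric(1))
    sum(p.adjust(pv, "BH") < fdr) >= min_markers
  }
  all_separable <- function(assign, k) {
    for (c1 in seq_len(k - 1))
      for (c2 in seq(c1 + 1, k))
        if (!pair_separable(assign == c1, assign == c2)) return(FALSE)
    TRUE
  }

  iterations <- 0L
  for (k in seq(init_groups, 2)) {
    iterations <- iterations + 1L
    assign <- .canonical_cluster_ids(cutree(hc, k = k), barcodes)
    qualified <- all_separable(assign, k)
    if (qualified || k == 2) {
      dt <- diff_for(assign, k)
      if (!qualified)
        warning("no cut down to 2 groups qualifies; returning the 2-group cut")
      return(structure(list(
        clusters = setNames(assign, barcodes),
        diff_proteins = dt, k = k, iterations = iterations,
        all_qualified = qualified),
        class = "cluster_assignment"))
    }
  }
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> %d clusters over %d cells (%d refinement iterations%s)\n",
    x$k, length(x$clusters), x$iterations,
    if (x$all_qualified) "" else "; UNQUALIFIED 2-group fallback"))
  invisible(x)
}

#' Differential TF activity between clusters
#'
#' For each TF and cluster: two-sample Wilcoxon rank-sum test of cells in
#' the cluster vs all other cells, effect size = difference of means,
#' BH-FDR across TFs within each cluster.
#'
#' @param A TFs x cells activity matrix.
#' @param clusters a `cluster_assignment` or named cluster-id vector
#'   matching A's cells.
#' @return Tibble (tf, cluster, effect, p, q), ordered by |effect| within
#'   cluster.
#' @export
differential_activity <- function(A, clusters) {
  A <- as.matrix(A)
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$clusters
        else clusters
  if (!is.null(colnames(A)) && !is.null(names(cl)))
    cl <- cl[colnames(A)]
  stopifnot(length(cl) == ncol(A))
  ids <- sort(unique(cl))
  if (length(ids) < 2) stop("need >= 2 clusters")
  tfs <- rownames(A); if (is.null(tfs)) tfs <- paste0("TF", seq_len(nrow(A)))
  out <- do.call(rbind, lapply(ids, function(g) {
    inside <- cl == g
    res <- t(vapply(seq_len(nrow(A)), function(q) {
      xi <- A[q, inside]; xo <- A[q, !inside]
      if (length(unique(c(xi, xo))) == 1L) return(c(0, 1))
      p <- suppressWarnings(wilcox.test(xi, xo, exact = FALSE)$p.value)
      c(mean(xi) - mean(xo), p)
    }, numeric(2)))
    tibble::tibble(tf = tfs, cluster = g, effect = res[, 1], p = res[, 2],
                   q = p.adjust(res[, 2], "BH"))
  }))
  out[order(out$cluster, -abs(out$effect)), ]
}

#' Top differential TFs per cluster
#'
#' @param diff tibble from [differential_activity()].
#' @param top_k TFs per cluster, ranked by |effect| (default 20).
#' @return Subset tibble (union of the per-cluster top-k TFs).
#' @export
top_differential <- function(diff, top_k = 20) {
  picked <- unlist(lapply(split(diff, diff$cluster), function(d)
    d$tf[order(-abs(d$effect))][seq_len(min(top_k, nrow(d)))]))
  diff[diff$tf %in% unique(picked), ]
}
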