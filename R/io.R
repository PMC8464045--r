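#' Raw UMI/ADT count container
#'
#' A light S3 wrapper around a features x cells count matrix with a modality
#' tag. Counts are kept sparse (`dgCMatrix`) for RNA-scale data.
#'
#' @param mat non-negative integer matrix (features x cells), base or Matrix.
#' @param feature_ids character vector of unique feature identifiers.
#' @param cell_barcodes character vector of unique cell barcodes.
#' @param modality `"rna"` or `"adt"`.
#' @return An object of class `raw_counts`.
#' @export
raw_counts <- function(mat, feature_ids = rownames(mat),
                       cell_barcodes = colnames(mat),
                       modality = c("rna", "adt")) {
  modality <- match.arg(modality)
  if (is.null(feature_ids) || is.null(cell_barcodes))
    stop("feature_ids and cell_barcodes are required")
  if (anyDuplicated(feature_ids))
    stop("feature_ids must be unique (disambiguate before construction)")
  if (anyDuplicated(cell_barcodes)) stop("cell_barcodes must be unique")
  m <- Matrix::Matrix(mat, sparse = TRUE)
  if (!is(m, "dMatrix")) m <- as(m, "dMatrix")   # pattern/logical -> numeric
  m <- as(m, "CsparseMatrix")
  if (nrow(m) != length(feature_ids) || ncol(m) != length(cell_barcodes))
    stop("matrix dimensions do not match feature/barcode lists")
  v <- m@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("counts must be non-negative integers")
  dimnames(m) <- list(feature_ids, cell_barcodes)
  structure(list(matrix = m,
                 feature_ids = feature_ids,
                 cell_barcodes = cell_barcodes,
                 modality = modality),
            class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  cat(sprintf("<raw_counts> %s: %d features x %d cells, %d nonzeros\n",
              x$modality, nrow(x$matrix), ncol(x$matrix),
              Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' @export
dim.raw_counts <- function(x) dim(x$matrix)

.read_maybe_gz <- function(dir, base) {
  for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz"))))
    if (file.exists(f)) return(f)
  stop("missing file: ", file.path(dir, base), "[.gz]")
}

#' Read a count matrix from disk
#'
#' Supports CellRanger-style MTX triplet directories
#' (`matrix.mtx[.gz]` + `features.tsv[.gz]` + `barcodes.tsv[.gz]`) and dense
#' CSV/TSV with a header row of barcodes and feature ids in the first
#' column. Duplicate feature names are disambiguated deterministically by
#' appending `.1`, `.2`, ... in file order.
#'
#' @param path directory (for `mtx_dir`) or file path.
#' @param format one of `"auto"`, `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @param modality `"rna"` or `"adt"`.
#' @return A [raw_counts] object.
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "csv", "tsv"),
                        modality = c("rna", "adt")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.csv(\\.gz)?$", path)) "csv" else "tsv"
  }
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop("missing directory: ", path)
    mtx <- .read_maybe_gz(path, "matrix.mtx")
    fts <- .read_maybe_gz(path, "features.tsv")
    bcs <- .read_maybe_gz(path, "barcodes.tsv")
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
    feats <- read.delim(fts, header = FALSE, stringsAsFactors = FALSE)
    barcodes <- read.delim(bcs, header = FALSE, stringsAsFactors = FALSE)[[1]]
    ids <- feats[[min(2L, ncol(feats))]]
    if (nrow(m) != length(ids) || ncol(m) != length(barcodes))
      stop(sprintf(
        "format error: MTX header is %d x %d but %d features / %d barcodes listed",
        nrow(m), ncol(m), length(ids), length(barcodes)))
    raw_counts(m, make.unique(as.character(ids)), barcodes, modality)
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    sep <- if (format == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- make.unique(as.character(df[[1]]))
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    raw_counts(m, ids, colnames(df)[-1], modality)
  }
}

#' Write counts as a CellRanger-style MTX triplet
#'
#' @param counts a [raw_counts] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(inherits(counts, "raw_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts$matrix, file.path(dir, "matrix.mtx"))
  type <- if (counts$modality == "rna") "Gene Expression" else "Antibody Capture"
  write.table(
    data.frame(counts$feature_ids, counts$feature_ids, type),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(counts$cell_barcodes, file.path(dir, "barcodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Quality-control filter on cells by expressed-gene count
#'
#' Keeps cells whose number of genes with nonzero counts `g` satisfies
#' `min_genes <= g <= max_genes`; cells below the lower bound are typically
#' empty droplets/debris, cells above the upper bound likely doublets.
#'
#' @param rna a [raw_counts] object with `modality == "rna"`.
#' @param min_genes,max_genes inclusive bounds on expressed genes per cell.
#' @return Filtered [raw_counts]; removed barcodes in
#'   `attr(, "removed_barcodes")`.
#' @export
qc_filter_cells <- function(rna, min_genes = 300, max_genes = 5000) {
  stopifnot(inherits(rna, "raw_counts"))
  if (rna$modality != "rna") stop("qc_filter_cells expects RNA counts")
  g <- Matrix::colSums(rna$matrix > 0)
  keep <- g >= min_genes & g <= max_genes
  if (!any(keep))
    stop("all cells removed by QC; review min_genes/max_genes thresholds")
  out <- raw_counts(rna$matrix[, keep, drop = FALSE],
                    rna$feature_ids, rna$cell_barcodes[keep], "rna")
  attr(out, "removed_barcodes") <- rna$cell_barcodes[!keep]
  out
}

#' Optional gene prevalence filter
#'
#' Keeps genes with at least `min_umi` counts in at least `min_frac` of
#' cells. Off by default in the pipeline; exposed for sparse datasets.
#'
#' @param rna a [raw_counts] object.
#' @param min_umi minimum UMI count per cell to call a gene detected.
#' @param min_frac minimum fraction of cells in which the gene is detected.
#' @return Filtered [raw_counts].
#' @export
filter_genes_by_prevalence <- function(rna, min_umi = 3, min_frac = 0.01) {
  stopifnot(inherits(rna, "raw_counts"))
  frac <- Matrix::rowSums(rna$matrix >= min_umi) / ncol(rna$matrix)
  keep <- frac >= min_frac
  if (!any(keep)) stop("no genes pass the prevalence filter")
  raw_counts(rna$matrix[keep, , drop = FALSE],
             rna$feature_ids[keep], rna$cell_barcodes, rna$modality)
}

#' Read a TF -> target-gene prior edge list
#'
#' Two or three tab-separated columns: tf, gene and an optional sign (the
#' sign is read but not used; regulon membership is unsigned).
#'
#' @param path TSV path, with or without header (auto-detected by the
#'   column names `tf`/`gene`).
#' @return A data.frame with columns `tf`, `gene`.
#' @export
read_prior_edges <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  first <- read.delim(path, header = FALSE, nrows = 1,
                      stringsAsFactors = FALSE)
  has_header <- identical(tolower(as.character(first[[1]])), "tf")
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("tf", "gene")
  df[, c("tf", "gene")]
}

#' Read cell-type labels
#'
#' @param path two-column TSV (barcode, label), with or without header.
#' @return Named character vector: barcode -> label.
#' @export
read_cell_labels <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  first <- read.delim(path, header = FALSE, nrows = 1,
                      stringsAsFactors = FALSE)
  has_header <- identical(tolower(as.character(first[[1]])), "barcode")
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a GMT pathway file (MSigDB dialect)
#'
#' @param path GMT file: name, description, then member symbols per line.
#' @return Named list of character vectors (pathway -> members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}
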