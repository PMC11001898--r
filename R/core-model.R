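#' Construct a validated UMI count matrix
#'
#' The central container of the pipeline: a sparse genes-by-cells matrix of
#' non-negative integer UMI counts with unique gene symbols as rownames and
#' unique cell barcodes as colnames. On disk the Matrix Market representation
#' is 1-based (the format's convention); in memory all indexing is the usual
#' R 1-based indexing on the named dimensions.
#'
#' @param counts matrix or sparse Matrix, genes in rows, cells in columns.
#' @param genes character vector of gene symbols (defaults to rownames).
#' @param cells character vector of cell barcodes (defaults to colnames).
#' @return A `dgCMatrix` with class attribute `countmatrix`, validated.
#' @export
count_matrix <- function(counts, genes = rownames(counts), cells = colnames(counts)) {
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(genes) || is.null(cells)) {
    stop("count_matrix requires gene and cell identifiers")
  }
  if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
    stop("identifier lists do not match matrix dimensions")
  }
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  if (anyDuplicated(cells)) stop("duplicate cell barcodes")
  v <- m@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("counts must be non-negative integers")
  }
  dimnames(m) <- list(as.character(genes), as.character(cells))
  m
}

#' Build or complete per-cell annotation
#'
#' Ensures one metadata row per barcode of `counts`, in matrix column order,
#' and computes `n_feature` (genes with count > 0) and `percent_mt`
#' (percentage of UMIs from genes whose symbol starts with `mito_prefix`)
#' when absent. Mitochondrial genes are identified by symbol prefix because
#' annotation files rarely flag them; the prefix is configurable and matched
#' case-sensitively.
#'
#' @param counts count matrix from [count_matrix()].
#' @param metadata data.frame with columns `cell`, `sample`, `group`
#'   (T1..T5) and optionally `cell_type`, `n_feature`, `percent_mt`.
#' @param mito_prefix prefix identifying mitochondrial gene symbols
#'   (default `"MT-"`).
#' @return data.frame with columns cell, sample, group (ordered factor),
#'   cell_type, n_feature, percent_mt; rows aligned to `colnames(counts)`.
#' @export
cell_annotation <- function(counts, metadata, mito_prefix = "MT-") {
  need <- c("cell", "sample", "group")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$cell)) stop("duplicate barcodes in metadata")
  absent <- setdiff(colnames(counts), metadata$cell)
  if (length(absent) > 0) {
    stop("missing annotation for ", length(absent), " barcode(s), e.g. ", absent[1])
  }
  ann <- metadata[match(colnames(counts), metadata$cell), , drop = FALSE]
  rownames(ann) <- ann$cell
  ann$group <- as_group_factor(ann$group)
  if (is.null(ann$cell_type)) ann$cell_type <- NA_character_
  ann$cell_type <- as.character(ann$cell_type)
  if (is.null(ann$n_feature)) {
    ann$n_feature <- Matrix::colSums(counts > 0)
  }
  if (is.null(ann$percent_mt)) {
    mito <- startsWith(rownames(counts), mito_prefix)
    tot <- Matrix::colSums(counts)
    mt <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
    ann$percent_mt <- ifelse(tot > 0, 100 * mt / tot, 0)
  }
  stopifnot(all(ann$n_feature >= 0), all(ann$percent_mt >= -1e-9 & ann$percent_mt <= 100 + 1e-9))
  ann
}

#' Read a 10x-style expression bundle
#'
#' Reads a Matrix Market coordinate file plus one-per-line gene and barcode
#' files and a metadata TSV, returning a validated `(counts, annotation)`
#' pair. Matrix entries must be non-negative integers; row/column order of
#' the returned counts follows the identifier files.
#'
#' @param mtx_path Matrix Market (.mtx) coordinate file, genes x cells.
#' @param genes_path one gene symbol per line (first TSV column used).
#' @param barcodes_path one barcode per line.
#' @param metadata_path TSV with header `cell, sample, group[, cell_type, ...]`.
#' @param mito_prefix passed to [cell_annotation()].
#' @return list with elements `counts` and `annotation`.
#' @export
read_expression_bundle <- function(mtx_path, genes_path, barcodes_path,
                                   metadata_path, mito_prefix = "MT-") {
  m <- Matrix::readMM(mtx_path)
  genes <- read.delim(genes_path, header = FALSE, stringsAsFactors = FALSE)[, 1]
  cells <- read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)[, 1]
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("dimension mismatch: matrix is ", nrow(m), "x", ncol(m),
         " but identifier files list ", length(genes), " genes / ",
         length(cells), " barcodes")
  }
  counts <- count_matrix(m, genes, cells)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  ann <- cell_annotation(counts, meta, mito_prefix = mito_prefix)
  list(counts = counts, annotation = ann)
}

#' Write an expression bundle to disk
#'
#' Inverse of [read_expression_bundle()]; writes MTX + genes/barcodes TSV +
#' metadata TSV into `dir` using the standard 10x-style file names.
#'
#' @param counts count matrix.
#' @param annotation per-cell annotation data.frame.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_expression_bundle <- function(counts, annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mtx = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  Matrix::writeMM(counts, paths["mtx"])
  writeLines(rownames(counts), paths["genes"])
  writeLines(colnames(counts), paths["barcodes"])
  write_results(annotation, paths["metadata"])
  invisible(paths)
}

#' Read gene sets from GMT or two-column CSV
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; the CSV form
#' has columns `set_name, gene`. Genes are de-duplicated within a set; file
#' order of sets and genes is preserved. Symbols are matched case-sensitively
#' throughout the package.
#'
#' @param path GMT (`.gmt`) or CSV file.
#' @return Named list of character vectors (one per gene set).
#' @export
read_gene_sets <- function(path) {
  is_gmt <- grepl("\\.gmt$", path, ignore.case = TRUE)
  if (!is_gmt) {
    # peek: a comma in the first line means CSV
    first <- readLines(path, n = 1)
    is_gmt <- !grepl(",", first)
  }
  sets <- list()
  if (is_gmt) {
    for (line in readLines(path)) {
      if (!nzchar(trimws(line))) next
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) stop("malformed GMT line: ", substr(line, 1, 60))
      genes <- unique(parts[-(1:2)])
      genes <- genes[nzchar(genes)]
      if (length(genes) == 0) stop("empty gene set: ", parts[1])
      sets[[parts[1]]] <- genes
    }
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("set_name", "gene") %in% names(tab))) {
      stop("CSV gene sets need columns set_name, gene")
    }
    for (nm in unique(tab$set_name)) {
      genes <- unique(tab$gene[tab$set_name == nm])
      genes <- genes[nzchar(genes)]
      if (length(genes) == 0) stop("empty gene set: ", nm)
      sets[[nm]] <- genes
    }
  }
  if (length(sets) == 0) stop("no gene sets in ", path)
  sets
}

#' Write a tabular result as TSV
#'
#' Header + tab-separated rows, floats at 6 significant digits, row order as
#' given (deterministic). Used for every tabular output of the pipeline.
#'
#' @param table data.frame.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  tab <- as.data.frame(table)
  for (j in seq_along(tab)) {
    if (is.double(tab[[j]])) tab[[j]] <- signif(tab[[j]], 6)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
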