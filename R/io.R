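# Readers and writers for the external formats the pipeline touches:
# delimited count tables, GMT gene-set files, and MatrixMarket sparse
# single-cell triples. All readers validate strictly and preserve file
# order; none silently reorders genes, samples or cells.

#' Validate a genes-by-samples count matrix
#'
#' Enforces the invariants every bulk count matrix in this package must
#' satisfy: numeric matrix, unique gene and sample identifiers, no negative
#' and no non-integer entries.
#'
#' @param counts numeric matrix (genes in rows, samples in columns) with
#'   rownames and colnames.
#' @return the validated matrix, invisibly usable as before.
#' @export
validate_counts <- function(counts) {
  check_matrix_ids(counts, "count matrix")
  bad <- which(!is_whole(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- rownames(counts)[bad[1, 1]]
    s <- colnames(counts)[bad[1, 2]]
    stop2("invalid count at gene '", g, "', sample '", s, "': entries must ",
          "be non-negative integers (found ", counts[bad[1, 1], bad[1, 2]], ")")
  }
  counts
}

#' Read a delimited count matrix
#'
#' Reads a text table whose first row holds sample identifiers and whose
#' first column holds gene identifiers. Both a bare header (one field per
#' sample) and a header with a leading label for the gene-id column are
#' accepted. Row and column order of the file is preserved exactly.
#'
#' @param path path to the table.
#' @param delimiter field separator, default tab.
#' @return validated numeric matrix of counts (genes x samples).
#' @seealso [write_count_matrix()] for the inverse operation.
#' @export
read_count_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L) stop2("malformed count table (need header plus at least one gene row): ", path)
  header <- strsplit(lines[1], delimiter, fixed = TRUE)[[1]]
  body1  <- strsplit(lines[2], delimiter, fixed = TRUE)[[1]]
  if (length(body1) < 2L) stop2("malformed count table: data rows need a gene id plus counts")
  if (length(header) == length(body1) - 1L) {
    sample_ids <- header
  } else if (length(header) == length(body1)) {
    sample_ids <- header[-1]
  } else {
    stop2("malformed header: ", length(header), " fields for data rows of ",
          length(body1), " fields")
  }
  sample_ids <- trimws(sample_ids)
  dat <- utils::read.table(path, sep = delimiter, skip = 1L, header = FALSE,
                           colClasses = c("character", rep("numeric", length(sample_ids))),
                           quote = "", comment.char = "", stringsAsFactors = FALSE)
  gene_ids <- trimws(dat[[1]])
  counts <- as.matrix(dat[, -1, drop = FALSE])
  dimnames(counts) <- list(gene_ids, sample_ids)
  validate_counts(counts)
}

#' Write a count matrix as a delimited table
#'
#' @param counts validated genes x samples matrix.
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @export
write_count_matrix <- function(counts, path, delimiter = "\t") {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param name gene-set name.
#' @param genes character vector of gene identifiers (at least one).
#' @param description optional free-text description.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop2("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warn2("gene set '", name, "' contains duplicate genes; deduplicated")
    genes <- unique(genes)
  }
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One gene set per line in the Broad GMT dialect:
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are deduplicated with a warning; an empty file yields an empty list.
#'
#' @param path path to the GMT file.
#' @return named list of [gene_set()] objects, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop2("GMT format error at line ", i,
            ": need name, description and at least one gene (",
            length(fields), " fields found)")
    }
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)], description = fields[2])
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na", s$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a sparse single-cell count container
#'
#' @param counts genes x cells sparse (or dense) non-negative matrix with
#'   dimnames.
#' @param annotations named character vector mapping cell id to cell-type
#'   label; cells without an entry are labelled `"unassigned"`.
#' @return an object of class `sparse_cell_matrix` with elements `counts`
#'   (a `dgCMatrix`) and `annotations` (one label per cell, cell order of
#'   the matrix).
#' @export
sparse_cell_matrix <- function(counts, annotations = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop2("sparse cell matrix needs gene ids as rownames and cell barcodes as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop2("duplicate gene ids in sparse cell matrix")
  if (anyDuplicated(colnames(counts))) stop2("duplicate cell barcodes in sparse cell matrix")
  if (any(counts@x < 0)) stop2("negative entries in sparse cell matrix")
  cell_ids <- colnames(counts)
  lab <- rep("unassigned", length(cell_ids))
  names(lab) <- cell_ids
  if (!is.null(annotations) && length(annotations) > 0) {
    unknown <- setdiff(names(annotations), cell_ids)
    if (length(unknown) > 0) {
      stop2("annotated cell ids absent from the matrix: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    }
    lab[names(annotations)] <- as.character(annotations)
  }
  structure(list(counts = counts, annotations = lab),
            class = "sparse_cell_matrix")
}

#' @export
print.sparse_cell_matrix <- function(x, ...) {
  cat("Sparse cell matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells, ", length(x$counts@x), " stored entries\n", sep = "")
  tab <- table(x$annotations)
  cat("Annotations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a sparse single-cell matrix from a MatrixMarket triple
#'
#' Reads the standard trio (coordinate `.mtx` matrix, one-gene-per-line
#' features file, one-barcode-per-line barcodes file) plus an optional
#' two-column annotation table (`cell_id<TAB>label`, no header). In-file
#' MatrixMarket indices are 1-based (the format standard); in memory the
#' object behaves like any R matrix. Cells lacking an annotation get the
#' label `"unassigned"`.
#'
#' @param matrix_path MatrixMarket coordinate file (genes x cells).
#' @param features_path one gene identifier per line (a multi-column
#'   features file is accepted; the first column is used).
#' @param barcodes_path one cell barcode per line.
#' @param annotations_path optional two-column table mapping barcodes to
#'   cell-type labels.
#' @return a [sparse_cell_matrix()].
#' @export
read_sparse_cells <- function(matrix_path, features_path, barcodes_path,
                              annotations_path = NULL) {
  for (p in c(matrix_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop2("file not found: ", p)
  }
  m <- Matrix::readMM(matrix_path)
  feats <- strsplit(readLines(features_path), "\t", fixed = TRUE)
  gene_ids <- trimws(vapply(feats, `[[`, "", 1L))
  barcodes <- trimws(readLines(barcodes_path))
  if (length(gene_ids) != nrow(m)) {
    stop2("dimension mismatch: matrix has ", nrow(m), " rows but features ",
          "file lists ", length(gene_ids), " genes")
  }
  if (length(barcodes) != ncol(m)) {
    stop2("dimension mismatch: matrix has ", ncol(m), " columns but barcodes ",
          "file lists ", length(barcodes), " cells")
  }
  dimnames(m) <- list(gene_ids, barcodes)
  ann <- NULL
  if (!is.null(annotations_path)) {
    if (!file.exists(annotations_path)) stop2("file not found: ", annotations_path)
    tab <- utils::read.table(annotations_path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop2("annotation table needs two columns: cell_id, label")
    ann <- stats::setNames(tab[[2]], trimws(tab[[1]]))
  }
  sparse_cell_matrix(m, ann)
}

#' Write a sparse single-cell matrix as a MatrixMarket triple
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `annotations.tsv`
#' into a directory, in the dialect [read_sparse_cells()] reads back.
#'
#' @param x a [sparse_cell_matrix()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_sparse_cells <- function(x, dir) {
  stopifnot(inherits(x, "sparse_cell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(cell_id = colnames(x$counts), label = unname(x$annotations)),
    file.path(dir, "annotations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
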