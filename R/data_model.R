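#' Construct a gene-by-cell expression matrix
#'
#' Thin S3 container around a dense base matrix holding genes in rows and
#' cells in columns, together with a layer tag tracking the preprocessing
#' state and a platform tag used to decide which side of a matching run
#' receives cluster-summary weighting.
#'
#' @param values numeric matrix, genes x cells, non-negative, with unique
#'   rownames (gene symbols) and colnames (cell identifiers).
#' @param layer one of `"counts"`, `"logCPM"`, `"rescaled"`, `"normalized"`.
#' @param platform one of `"smartseq"`, `"tenx"`, `"spatial"`, `"other"`.
#' @return An object of class `gene_matrix`.
#' @export
gene_matrix <- function(values,
                        layer = c("counts", "logCPM", "rescaled", "normalized"),
                        platform = c("other", "smartseq", "tenx", "spatial")) {
  layer <- match.arg(layer)
  platform <- match.arg(platform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(values < 0)) stop("expression values must be non-negative")
  if (layer == "normalized" && any(values > 1 + 1e-12))
    stop("normalized layer requires values in [0, 1]")
  structure(list(values = values, layer = layer, platform = platform),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %d genes x %d cells, layer = %s, platform = %s\n",
              nrow(x$values), ncol(x$values), x$layer, x$platform))
  invisible(x)
}

#' @export
dim.gene_matrix <- function(x) dim(x$values)

#' Construct per-cell cluster labels
#'
#' @param cells character vector of cell identifiers.
#' @param clusters character or factor of cluster names, one per cell.
#' @return Named factor (names = cell ids) of class `cluster_labels`.
#' @export
cluster_labels <- function(cells, clusters) {
  cells <- as.character(cells)
  if (anyDuplicated(cells))
    stop("duplicate cell ids in labels: ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "))
  if (length(cells) != length(clusters))
    stop("cells and clusters must have equal length")
  f <- factor(as.character(clusters))
  if (any(is.na(f))) stop("every cell must have a cluster label")
  names(f) <- cells
  class(f) <- c("cluster_labels", "factor")
  f
}

#' @export
print.cluster_labels <- function(x, ...) {
  sizes <- table(unclass(x))
  cat(sprintf("<cluster_labels> %d cells in %d clusters\n",
              length(x), length(sizes)))
  print(sizes)
  invisible(x)
}

#' Cluster sizes of a labeling
#' @param labels a [cluster_labels()] object.
#' @return Named integer vector of cells per cluster.
#' @export
cluster_sizes <- function(labels) {
  tab <- table(factor(labels, levels = levels(labels)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Construct a marker gene set
#'
#' @param markers character vector of gene symbols (unique, length >= 2).
#' @param group_of optional named character vector mapping each marker to
#'   the cluster it defines; used only to order barcode plots.
#' @return Object of class `marker_set`.
#' @export
marker_set <- function(markers, group_of = NULL) {
  markers <- as.character(markers)
  if (anyDuplicated(markers))
    stop("duplicate marker genes: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  if (length(markers) < 2) stop("need at least 2 marker genes")
  if (!is.null(group_of)) {
    group_of <- group_of[markers]
    names(group_of) <- markers
  }
  structure(list(markers = markers, group_of = group_of),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers%s\n", length(x$markers),
              if (is.null(x$group_of)) "" else " (grouped by cluster)"))
  invisible(x)
}

read_table_expr <- function(path, sep, cells_as_rows) {
  df <- read.csv(path, sep = sep, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (cells_as_rows) m <- t(m)
  m
}

#' Read an expression matrix and its cluster labels
#'
#' Supported layouts: dense CSV/TSV with a header row of cell ids and gene
#' ids in the first column (set `cells_as_rows = TRUE` for the transposed
#' layout), or MatrixMarket triplet with `genes.txt` / `barcodes.txt`
#' sidecars (one id per line) next to the `.mtx` file. Labels are a
#' two-column table `(cell_id, cluster)`.
#'
#' Cells present in the expression matrix but absent from the labels (or
#' vice versa) are a consistency error; the offending ids are named.
#'
#' @param expr_path path to the expression file.
#' @param labels_path path to the label file (CSV, two columns).
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @param cells_as_rows dense layouts only: cells in rows on disk.
#' @param genes_path,cells_path MTX sidecars; default `genes.txt` and
#'   `barcodes.txt` beside the matrix file.
#' @param layer,platform tags forwarded to [gene_matrix()].
#' @return `list(matrix = gene_matrix, labels = cluster_labels)`.
#' @export
read_expression <- function(expr_path, labels_path,
                            format = c("csv", "tsv", "mtx"),
                            cells_as_rows = FALSE,
                            genes_path = NULL, cells_path = NULL,
                            layer = "counts", platform = "other") {
  format <- match.arg(format)
  for (p in c(expr_path, labels_path))
    if (!file.exists(p)) stop("file not found: ", p)
  if (format == "mtx") {
    if (is.null(genes_path))
      genes_path <- file.path(dirname(expr_path), "genes.txt")
    if (is.null(cells_path))
      cells_path <- file.path(dirname(expr_path), "barcodes.txt")
    for (p in c(genes_path, cells_path))
      if (!file.exists(p)) stop("MTX sidecar not found: ", p)
    m <- as.matrix(Matrix::readMM(expr_path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
  } else {
    m <- read_table_expr(expr_path, if (format == "csv") "," else "\t",
                         cells_as_rows)
  }
  lab <- read.csv(labels_path, check.names = FALSE,
                  colClasses = "character")
  if (ncol(lab) < 2) stop("label file must have (cell_id, cluster) columns")
  labels <- cluster_labels(lab[[1]], lab[[2]])
  missing_lab <- setdiff(colnames(m), names(labels))
  extra_lab <- setdiff(names(labels), colnames(m))
  if (length(missing_lab) || length(extra_lab))
    stop("label/expression cell mismatch; missing from labels: ",
         paste(missing_lab, collapse = ", "),
         "; missing from expression: ",
         paste(extra_lab, collapse = ", "))
  labels <- labels[colnames(m)]
  class(labels) <- c("cluster_labels", "factor")
  list(matrix = gene_matrix(m, layer = layer, platform = platform),
       labels = labels)
}

#' Write an expression matrix to CSV/TSV
#'
#' Values are written with 17 significant digits so a read/write round trip
#' is bit-identical.
#'
#' @param x a [gene_matrix()].
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_expression <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "gene_matrix"))
  v <- x$values
  chr <- matrix(formatC(v, digits = 17, format = "g"), nrow(v),
                dimnames = dimnames(v))
  df <- data.frame(gene = rownames(v), chr, check.names = FALSE)
  write.table(df, path, sep = if (format == "csv") "," else "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cluster labels to CSV
#' @param labels a [cluster_labels()] object.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  write.csv(data.frame(cell_id = names(labels),
                       cluster = as.character(labels)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker gene list
#'
#' Plain text, one gene symbol per line; an optional second
#' whitespace/comma-separated column gives the defining cluster.
#'
#' @param path marker file.
#' @return A [marker_set()].
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,\t ]+")
  markers <- vapply(parts, `[`, "", 1)
  groups <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  if (all(is.na(groups))) {
    marker_set(markers)
  } else {
    marker_set(markers, stats::setNames(groups, markers))
  }
}

#' Library-size normalize counts to log2(CPM + pseudocount)
#'
#' Each cell's counts are scaled to counts per million and log2-transformed:
#' `log2(pseudocount + 1e6 * count / total)`. The default pseudocount of 1
#' keeps zero counts at exactly 0 and all values finite.
#'
#' @param x a [gene_matrix()] with `layer = "counts"`.
#' @param pseudocount added inside the log; set to 0 for a bare log2(CPM)
#'   (zeros then map to `-Inf` and are reset to 0).
#' @return A `gene_matrix` with `layer = "logCPM"`.
#' @export
cpm_log2 <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "gene_matrix"))
  if (x$layer != "counts")
    stop("cpm_log2 expects layer 'counts', got '", x$layer, "'")
  totals <- colSums(x$values)
  if (any(totals <= 0))
    stop("cells with zero total count: ",
         paste(colnames(x$values)[totals <= 0], collapse = ", "))
  cpm <- sweep(x$values, 2, totals, "/") * 1e6
  v <- log2(pseudocount + cpm)
  if (pseudocount < 1) {
    # keep the matrix non-negative: zeros and sub-1-CPM values floor at 0
    v[x$values == 0] <- 0
    v <- pmax(v, 0)
  }
  gene_matrix(v, layer = "logCPM", platform = x$platform)
}

#' Project an expression matrix into a marker feature space
#'
#' Returns a matrix whose rows are exactly the marker genes in marker-set
#' order. Markers absent from the input are an error under
#' `missing_policy = "error"`; under `"zero_fill"` (the default, since
#' cross-platform gene panels routinely lack genes) they become all-zero
#' rows and a warning lists them. Gene symbols are matched case-sensitively.
#'
#' @param x a [gene_matrix()].
#' @param markers a [marker_set()] or character vector.
#' @param missing_policy `"zero_fill"` or `"error"`.
#' @return A `gene_matrix` restricted to the marker space.
#' @export
project_to_markers <- function(x, markers,
                               missing_policy = c("zero_fill", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(x, "gene_matrix"))
  if (!inherits(markers, "marker_set")) markers <- marker_set(markers)
  mk <- markers$markers
  absent <- setdiff(mk, rownames(x$values))
  if (length(absent) == length(mk))
    stop("no marker genes present in the expression matrix")
  if (length(absent)) {
    if (missing_policy == "error")
      stop("markers absent from expression matrix: ",
           paste(absent, collapse = ", "))
    warning("zero-filling markers absent from expression matrix: ",
            paste(absent, collapse = ", "))
  }
  out <- matrix(0, length(mk), ncol(x$values),
                dimnames = list(mk, colnames(x$values)))
  present <- intersect(mk, rownames(x$values))
  out[present, ] <- x$values[present, , drop = FALSE]
  gene_matrix(out, layer = x$layer, platform = x$platform)
}
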