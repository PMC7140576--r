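#' Construct a library sheet
#'
#' @param library_id,genotype,tissue,replicate equal-length vectors describing
#'   each RNA-seq library. (genotype, tissue, replicate) must be unique.
#' @return data.frame of class `library_sheet`.
#' @export
library_sheet <- function(library_id, genotype, tissue, replicate) {
  df <- data.frame(library_id = as.character(library_id),
                   genotype = as.character(genotype),
                   tissue = as.character(tissue),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$library_id)) stop("duplicated library_id")
  if (anyDuplicated(df[, c("genotype", "tissue", "replicate")])) {
    stop("(genotype, tissue, replicate) combinations must be unique")
  }
  class(df) <- c("library_sheet", "data.frame")
  df
}

#' Read a library sheet TSV
#'
#' Expects a header with columns `library_id`, `genotype`, `tissue`,
#' `replicate`.
#' @param path TSV file.
#' @return a [library_sheet()].
#' @export
read_library_sheet <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  library_sheet(tab$library_id, tab$genotype, tab$tissue, tab$replicate)
}

#' Construct an exon-level count matrix
#'
#' @param counts non-negative integer matrix, exons x libraries; row names are
#'   exon IDs, column names library IDs.
#' @param exons data.frame with columns `exon_id`, `gene_id`, `length` (bp,
#'   >= 1); one row per count-matrix row.
#' @param libraries a [library_sheet()] covering every column.
#' @return object of class `exon_counts`.
#' @export
exon_counts <- function(counts, exons, libraries) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- exons$exon_id
  if (!identical(rownames(counts), as.character(exons$exon_id))) {
    stop("count matrix rows must match exons$exon_id, in order")
  }
  if (!all(colnames(counts) %in% libraries$library_id)) {
    stop("count matrix columns absent from the library sheet: ",
         paste(setdiff(colnames(counts), libraries$library_id), collapse = ", "))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(exons$length < 1)) stop("exon lengths must be >= 1")
  libraries <- libraries[match(colnames(counts), libraries$library_id), , drop = FALSE]
  rownames(libraries) <- NULL
  structure(list(counts = counts,
                 exons = as.data.frame(exons, stringsAsFactors = FALSE),
                 libraries = libraries,
                 dropped_genes = character(0)),
            class = "exon_counts")
}

#' @export
print.exon_counts <- function(x, ...) {
  cat(sprintf("exon_counts: %d exons x %d libraries (%d genes)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$exons$gene_id))))
  invisible(x)
}

#' Read an exon count matrix TSV
#'
#' Wide layout: columns `exon_id`, `gene_id`, `length`, then one column per
#' library.
#' @param path TSV file with header.
#' @param libraries a [library_sheet()].
#' @return an [exon_counts()] object.
#' @export
read_exon_counts <- function(path, libraries) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  meta_cols <- c("exon_id", "gene_id", "length")
  if (!all(meta_cols %in% names(tab))) {
    stop("exon count table must have columns exon_id, gene_id, length")
  }
  lib_cols <- setdiff(names(tab), meta_cols)
  m <- as.matrix(tab[, lib_cols, drop = FALSE])
  rownames(m) <- tab$exon_id
  exon_counts(m, tab[, meta_cols], libraries)
}

#' Drop short exons
#'
#' Exons shorter than `min_len` bp are removed (strict `<`); with 50 bp reads,
#' alignment to sub-read-length exons is unreliable. Genes losing all their
#' exons are recorded in the returned object's `dropped_genes`.
#'
#' @param m an [exon_counts()] object.
#' @param min_len minimum retained exon length in bp (default 50).
#' @return filtered [exon_counts()] object.
#' @export
filter_short_exons <- function(m, min_len = 50) {
  keep <- m$exons$length >= min_len
  before <- unique(m$exons$gene_id)
  m$counts <- m$counts[keep, , drop = FALSE]
  m$exons <- m$exons[keep, , drop = FALSE]
  rownames(m$exons) <- NULL
  m$dropped_genes <- union(m$dropped_genes, setdiff(before, m$exons$gene_id))
  m
}

#' Per-exon TPM normalization
#'
#' For each library, every exon's count is divided by its length (a rate), and
#' rates are rescaled to sum to one million. A library with zero counts
#' everywhere yields all-zero TPM.
#'
#' @param m an [exon_counts()] object (short exons already filtered).
#' @return object of class `exon_tpm`: list with `values` (exons x libraries
#'   TPM matrix), `exons`, `libraries`.
#' @export
tpm <- function(m) {
  rates <- m$counts / m$exons$length
  totals <- colSums(rates)
  scale <- ifelse(totals > 0, 1e6 / totals, 0)
  vals <- sweep(rates, 2L, scale, `*`)
  structure(list(values = vals, exons = m$exons, libraries = m$libraries,
                 dropped_genes = m$dropped_genes),
            class = "exon_tpm")
}

#' Gene-level expression: mean exon TPM
#'
#' Per library, a gene's expression is the arithmetic mean of its retained
#' exons' TPM values. Genes with no retained exons are absent from the result
#' (and excluded downstream).
#'
#' @param et an `exon_tpm` object from [tpm()].
#' @param min_exon_len,floor recorded configuration (defaults 50 bp, 0.01 TPM).
#' @return object of class `gene_expr`: list with `values` (genes x libraries),
#'   `libraries`, `config`, `missing_genes`.
#' @export
gene_expression <- function(et, min_exon_len = 50, floor = 0.01) {
  gene <- et$exons$gene_id
  sums <- rowsum(et$values, group = gene, reorder = TRUE)
  n_ex <- as.vector(table(gene)[rownames(sums)])
  vals <- sums / n_ex
  structure(list(values = vals, libraries = et$libraries,
                 config = list(min_exon_len = min_exon_len, floor = floor),
                 missing_genes = et$dropped_genes),
            class = "gene_expr")
}

#' @export
print.gene_expr <- function(x, ...) {
  cat(sprintf("gene_expr: %d genes x %d libraries (floor %.3g TPM)\n",
              nrow(x$values), ncol(x$values), x$config$floor))
  invisible(x)
}

#' Expressed-gene set
#'
#' A gene is expressed when the mean of its gene-level values over the selected
#' libraries is at least `floor` (genes strictly below the floor are filtered
#' out; equality passes).
#'
#' @param g a `gene_expr` object.
#' @param floor expression floor in TPM (default 0.01).
#' @param libraries optional character vector of library IDs to average over
#'   (default: all).
#' @return character vector of expressed gene IDs.
#' @export
expressed_genes <- function(g, floor = 0.01, libraries = NULL) {
  v <- g$values
  if (!is.null(libraries)) {
    missing <- setdiff(libraries, colnames(v))
    if (length(missing)) stop("unknown libraries: ", paste(missing, collapse = ", "))
    v <- v[, libraries, drop = FALSE]
  }
  rownames(v)[rowMeans(v) >= floor]
}

#' Write a gene x library TPM table
#'
#' @param g a `gene_expr` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_expression <- function(g, path) {
  df <- data.frame(gene_id = rownames(g$values), g$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
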