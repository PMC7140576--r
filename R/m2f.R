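#' M2f configuration
#'
#' @param epsilon additive TPM pseudocount applied to both terms of every fold
#'   change (default 0.01, equal to the expression floor). `epsilon = 0` is
#'   supported for closed-form work but is undefined when both terms are 0.
#' @param genotype optional genotype label; when set, M2f is computed only over
#'   that genotype's libraries (the genotype whose annotation holds the split
#'   gene models, so the expression patterns match those used to build the
#'   annotation).
#' @return list of class `m2f_config`.
#' @export
m2f_config <- function(epsilon = 0.01, genotype = NULL) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  structure(list(epsilon = epsilon, genotype = genotype), class = "m2f_config")
}

#' Absolute log2 fold change
#'
#' `|log2((a + epsilon) / (b + epsilon))|`, symmetric in its arguments and 0
#' when they are equal. Vectorized.
#'
#' @param a,b non-negative expression values (TPM).
#' @param epsilon pseudocount; with `epsilon = 0`, `a = b = 0` is an error.
#' @return non-negative numeric vector.
#' @export
abs_l2fc <- function(a, b, epsilon = 0) {
  if (any(a < 0 | b < 0)) stop("expression values must be non-negative")
  if (epsilon == 0 && any(a == 0 & b == 0)) {
    stop("abs_l2fc undefined for a = b = 0 with epsilon = 0")
  }
  abs(log2((a + epsilon) / (b + epsilon)))
}

select_m2f_libraries <- function(expr, cfg) {
  libs <- expr$libraries
  if (!is.null(cfg$genotype)) {
    libs <- libs[libs$genotype == cfg$genotype, , drop = FALSE]
  }
  ids <- intersect(colnames(expr$values), libs$library_id)
  if (length(ids) == 0L) {
    stop("no libraries selected", if (!is.null(cfg$genotype))
      paste0(" for genotype '", cfg$genotype, "'") else "")
  }
  ids
}

#' M2f from a matrix of per-library expression values
#'
#' Core computation shared by candidates and null simulations: given a genes x
#' libraries matrix of TPM values for one candidate set, computes per library
#' the mean absolute log2 fold change over all unordered gene pairs, then the
#' flat mean over libraries (replicates enter as independent libraries).
#'
#' @param vals numeric matrix (>= 2 rows = genes, >= 1 column = libraries).
#' @param epsilon pseudocount.
#' @return list with `m2f`, `per_library` (named numeric), `n_libraries`.
#' @export
m2f_from_matrix <- function(vals, epsilon = 0.01) {
  if (nrow(vals) < 2L) stop("M2f requires at least 2 genes")
  if (ncol(vals) < 1L) stop("M2f requires at least 1 library")
  lv <- log2(vals + epsilon)
  if (any(!is.finite(lv))) {
    stop("M2f components must be finite: zero expression with epsilon = 0")
  }
  pairs <- combn(nrow(vals), 2L)
  d <- abs(lv[pairs[1L, ], , drop = FALSE] - lv[pairs[2L, ], , drop = FALSE])
  per_lib <- colMeans(d)
  list(m2f = mean(per_lib), per_library = per_lib, n_libraries = ncol(vals))
}

#' M2f for a candidate gene set
#'
#' The M2f statistic ("mean two-fold expression change across tissues") for a
#' set of two or more genes: within each selected library, the mean absolute
#' log2 fold change of gene-level TPM over all unordered gene pairs; M2f is the
#' flat mean of these per-library values across tissues and biological
#' replicates. Libraries are restricted to `cfg$genotype` when set.
#'
#' @param genes character vector of >= 2 gene IDs, all present in `expr`.
#' @param expr a `gene_expr` object (see [gene_expression()]).
#' @param cfg an [m2f_config()].
#' @return list with `m2f`, `per_library` (named by library ID),
#'   `n_libraries`, `genes`.
#' @export
candidate_m2f <- function(genes, expr, cfg = m2f_config()) {
  if (length(genes) < 2L) stop("M2f requires at least 2 genes")
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing)) {
    stop("gene(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  lib_ids <- select_m2f_libraries(expr, cfg)
  vals <- expr$values[genes, lib_ids, drop = FALSE]
  res <- m2f_from_matrix(vals, epsilon = cfg$epsilon)
  res$per_library <- setNames(res$per_library, lib_ids)
  res$genes <- genes
  res
}

#' M2f for every candidate in a table
#'
#' Computes [candidate_m2f()] per candidate row, restricting libraries to the
#' split-side genotype of each candidate (the annotation holding the multiple
#' gene models). Candidates whose genes are missing from the expression matrix
#' get `NA`.
#'
#' @param candidates candidate table from [build_split_candidates()].
#' @param expr_by_genotype named list of `gene_expr` objects keyed by genotype
#'   label (expression of each genotype's reads mapped to its own annotation).
#' @param epsilon pseudocount (default 0.01).
#' @return `candidates` with columns `m2f` and `n_libraries` added.
#' @export
m2f_table <- function(candidates, expr_by_genotype, epsilon = 0.01) {
  n <- nrow(candidates)
  m2f <- rep(NA_real_, n)
  nlib <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    gt <- candidates$split_annotation[i]
    expr <- expr_by_genotype[[gt]]
    if (is.null(expr)) stop("no expression matrix for genotype '", gt, "'")
    genes <- split_gene_field(candidates$split_genes[i])[[1]]
    if (!all(genes %in% rownames(expr$values))) next
    res <- candidate_m2f(genes, expr, m2f_config(epsilon = epsilon, genotype = gt))
    m2f[i] <- res$m2f
    nlib[i] <- res$n_libraries
  }
  candidates$m2f <- m2f
  candidates$n_libraries <- nlib
  candidates
}
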