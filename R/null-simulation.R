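#' Null-simulation configuration
#'
#' @param split_fraction fraction of eligible genes artificially split in two
#'   (default 0.20).
#' @param merged_fraction fraction of remaining genes paired with their
#'   adjacent upstream neighbor (default 0.30).
#' @param min_exons_for_split minimum exon count for a gene to be split, so
#'   each half keeps at least two exons (default 4).
#' @param split_percentile percentile of the split null used as the
#'   split-supported threshold (default 90).
#' @param merged_percentile percentile of the merged null used as the
#'   merge-supported threshold (default 10).
#' @param seed optional integer seed applied at the start of each simulation.
#' @return list of class `null_config`.
#' @export
null_config <- function(split_fraction = 0.20, merged_fraction = 0.30,
                        min_exons_for_split = 4, split_percentile = 90,
                        merged_percentile = 10, seed = NULL) {
  stopifnot(split_fraction > 0, split_fraction <= 1,
            merged_fraction > 0, merged_fraction <= 1,
            split_percentile > 0, split_percentile < 100,
            merged_percentile > 0, merged_percentile < 100,
            min_exons_for_split >= 4)
  structure(list(split_fraction = split_fraction,
                 merged_fraction = merged_fraction,
                 min_exons_for_split = as.integer(min_exons_for_split),
                 split_percentile = split_percentile,
                 merged_percentile = merged_percentile,
                 seed = seed),
            class = "null_config")
}

new_null_distribution <- function(kind, values, annotation_label, seed, n,
                                  genes = NULL) {
  structure(list(kind = kind, values = as.numeric(values),
                 annotation = annotation_label, seed = seed, n = n,
                 genes = genes),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("%s (%s): n = %d, median = %.3f\n",
              x$kind, x$annotation, x$n, median(x$values)))
  invisible(x)
}

#' Simulate the split null: artificially split single genes
#'
#' Null model for "these split genes are really one gene": real (non-candidate)
#' genes with at least `min_exons_for_split` retained exons are sampled without
#' replacement, each is split in two at a uniformly random internal exon
#' junction leaving at least two exons per side, each half's expression is the
#' mean of its exons' TPM per library, and the M2f of the two halves is
#' recorded. Observed candidate M2f values above this distribution's 90th
#' percentile are unlikely under a single underlying gene.
#'
#' @param ann the [annotation] holding the genes (the split-side annotation).
#' @param exon_tpm an `exon_tpm` object from [tpm()] for the same annotation.
#' @param exclude gene IDs to remove first (all split/merge candidate genes).
#' @param cfg a [null_config()]; `cfg$seed` (if set) seeds the sampling.
#' @param m2f_cfg an [m2f_config()]; its genotype restricts libraries.
#' @return a `null_distribution` of kind `split_null`.
#' @export
simulate_split_null <- function(ann, exon_tpm, exclude = character(0),
                                cfg = null_config(), m2f_cfg = m2f_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lib_ids <- select_m2f_libraries(exon_tpm, m2f_cfg)
  ex <- exon_tpm$exons
  ex_by_gene <- split(seq_len(nrow(ex)), ex$gene_id)
  n_ex <- lengths(ex_by_gene)
  eligible <- names(ex_by_gene)[n_ex >= cfg$min_exons_for_split]
  eligible <- setdiff(eligible, exclude)
  eligible <- sort(eligible)
  if (length(eligible) == 0L) stop("no genes eligible for artificial splitting")
  n_draw <- max(1L, floor(cfg$split_fraction * length(eligible)))
  picked <- sample(eligible, n_draw, replace = FALSE)

  vals <- exon_tpm$values[, lib_ids, drop = FALSE]
  m2f <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    # exon rows are ordered by genomic start within each gene (annotation
    # and read_exon_counts both guarantee this)
    idx <- ex_by_gene[[picked[i]]]
    k_max <- length(idx) - 2L
    k <- if (k_max == 2L) 2L else sample(2:k_max, 1L)
    left <- colMeans(vals[idx[seq_len(k)], , drop = FALSE])
    right <- colMeans(vals[idx[(k + 1L):length(idx)], , drop = FALSE])
    m2f[i] <- mean(abs(log2((left + m2f_cfg$epsilon) / (right + m2f_cfg$epsilon))))
  }
  new_null_distribution("split_null", m2f, ann$genotype, cfg$seed, n_draw,
                        genes = picked)
}

#' Simulate the merged null: real adjacent gene pairs
#'
#' Null model for "these split genes are really two distinct genes": real
#' (non-candidate, expressed) genes are sampled without replacement and each is
#' paired with the adjacent gene of next-lower rank on the same chromosome.
#' M2f is computed on the two original loci (no actual merging). Observed
#' candidate M2f values below this distribution's 10th percentile look more
#' alike than genuinely distinct neighbors do.
#'
#' Anchors that are rank 0 (no upstream neighbor), excluded, or whose neighbor
#' is excluded/unexpressed are ineligible; the realized n is reported.
#'
#' @param ann the [annotation] (split-side).
#' @param gene_expr a `gene_expr` object for the same annotation.
#' @param exclude gene IDs to remove first.
#' @param cfg a [null_config()].
#' @param m2f_cfg an [m2f_config()].
#' @return a `null_distribution` of kind `merged_null`.
#' @export
simulate_merged_null <- function(ann, gene_expr, exclude = character(0),
                                 cfg = null_config(), m2f_cfg = m2f_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  g <- ann$genes
  remaining <- setdiff(g$gene_id, exclude)
  expressed <- expressed_genes(gene_expr, floor = gene_expr$config$floor)

  gr <- g[g$gene_id %in% remaining, , drop = FALSE]
  # upstream neighbor = gene of next-lower rank on the same chromosome,
  # looked up in the full annotation's rank order
  key <- paste(g$chrom, g$rank)
  up_of <- setNames(g$gene_id, key)
  up_key <- paste(gr$chrom, gr$rank - 1L)
  neighbor <- unname(up_of[up_key])

  ok <- !is.na(neighbor) &
    gr$gene_id %in% expressed &
    neighbor %in% expressed &
    !(neighbor %in% exclude) &
    gr$gene_id %in% rownames(gene_expr$values) &
    neighbor %in% rownames(gene_expr$values)
  anchors <- gr$gene_id[ok]
  partners <- neighbor[ok]
  o <- order(anchors)
  anchors <- anchors[o]; partners <- partners[o]
  if (length(anchors) < 1L) {
    stop("no eligible adjacent expressed gene pairs for the merged null")
  }
  n_draw <- min(length(anchors),
                max(1L, floor(cfg$merged_fraction * length(remaining))))
  pick <- sample(seq_along(anchors), n_draw, replace = FALSE)

  lib_ids <- select_m2f_libraries(gene_expr, m2f_cfg)
  vals <- gene_expr$values[, lib_ids, drop = FALSE]
  a <- vals[anchors[pick], , drop = FALSE] + m2f_cfg$epsilon
  b <- vals[partners[pick], , drop = FALSE] + m2f_cfg$epsilon
  m2f <- rowMeans(abs(log2(a / b)))
  new_null_distribution("merged_null", unname(m2f), ann$genotype, cfg$seed,
                        n_draw,
                        genes = data.frame(anchor = anchors[pick],
                                           partner = partners[pick],
                                           stringsAsFactors = FALSE))
}

#' Linear-interpolation percentile
#'
#' On sorted values x(1..n), rank h = 1 + (n - 1) p / 100; the result
#' interpolates linearly between the flanking order statistics. The thresholds
#' reported by this package depend on this convention, so it is fixed here
#' rather than left to a quantile-type default.
#'
#' @param values non-empty numeric vector.
#' @param p percentile in \[0, 100\].
#' @return interpolated percentile.
#' @export
percentile <- function(values, p) {
  if (length(values) == 0L) stop("percentile of an empty vector")
  stopifnot(p >= 0, p <= 100)
  x <- sort(values)
  n <- length(x)
  h <- 1 + (n - 1) * p / 100
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1L] - x[lo])
}

#' Classification thresholds from simulated nulls
#'
#' Pools null M2f values across annotations (default) and takes the split
#' null's 90th percentile as `t_split` (above it, the split annotation is
#' supported) and the merged null's 10th percentile as `t_merge` (below it, the
#' single merged model is supported). With `pool = FALSE`, per-annotation
#' thresholds are also reported.
#'
#' @param split_nulls,merged_nulls a `null_distribution` or list of them.
#' @param cfg a [null_config()] supplying the percentiles.
#' @param pool pool values across annotations (default TRUE).
#' @return list of class `m2f_thresholds` with `t_merge`, `t_split`, `pooled`,
#'   `n_split`, `n_merge`, and (when `pool = FALSE`) `per_annotation`.
#' @export
compute_thresholds <- function(split_nulls, merged_nulls, cfg = null_config(),
                               pool = TRUE) {
  as_list <- function(x) if (inherits(x, "null_distribution")) list(x) else x
  split_nulls <- as_list(split_nulls)
  merged_nulls <- as_list(merged_nulls)
  sv <- unlist(lapply(split_nulls, `[[`, "values"))
  mv <- unlist(lapply(merged_nulls, `[[`, "values"))
  t_split <- percentile(sv, cfg$split_percentile)
  t_merge <- percentile(mv, cfg$merged_percentile)
  if (t_merge > t_split) {
    warning(sprintf("t_merge (%.3f) exceeds t_split (%.3f); every call will be decisive and none ambiguous",
                    t_merge, t_split))
  }
  out <- structure(list(t_merge = t_merge, t_split = t_split, pooled = pool,
                        n_split = length(sv), n_merge = length(mv)),
                   class = "m2f_thresholds")
  if (!pool) {
    per <- lapply(seq_along(split_nulls), function(i) {
      list(annotation = split_nulls[[i]]$annotation,
           t_split = percentile(split_nulls[[i]]$values, cfg$split_percentile),
           t_merge = percentile(merged_nulls[[i]]$values, cfg$merged_percentile))
    })
    out$per_annotation <- per
  }
  out
}

#' @export
print.m2f_thresholds <- function(x, ...) {
  cat(sprintf("M2f thresholds: t_merge = %.3f (merged-null 10th pct, n = %d), t_split = %.3f (split-null 90th pct, n = %d)%s\n",
              x$t_merge, x$n_merge, x$t_split, x$n_split,
              if (x$pooled) ", pooled" else ""))
  invisible(x)
}
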