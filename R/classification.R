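#' Classify M2f values against null thresholds
#'
#' Strict inequalities: `m2f < t_merge` supports the single merged gene model
#' (`merge_supported`), `m2f > t_split` supports the separate split models
#' (`split_supported`), anything between or equal to a threshold is
#' `ambiguous`. Vectorized.
#'
#' @param m2f numeric vector of finite, non-negative M2f values (NA allowed,
#'   propagated).
#' @param thresholds an `m2f_thresholds` object (see [compute_thresholds()]).
#' @return character vector of calls.
#' @export
classify_m2f <- function(m2f, thresholds) {
  out <- rep(NA_character_, length(m2f))
  known <- !is.na(m2f)
  out[known] <- "ambiguous"
  out[known & m2f < thresholds$t_merge] <- "merge_supported"
  out[known & m2f > thresholds$t_split] <- "split_supported"
  out
}

#' Call every candidate in a scored table
#'
#' Adds the M2f call and the supported annotation per candidate:
#' `merge_supported` supports the merged (single-gene) annotation,
#' `split_supported` the split (multi-gene) annotation, `ambiguous` neither.
#' Only testable candidates (all filters passed, M2f computed) are called.
#'
#' @param scored candidate table with an `m2f` column (see [m2f_table()]).
#' @param thresholds an `m2f_thresholds` object.
#' @return `scored` with `call` and `supported_annotation` columns.
#' @export
call_candidates <- function(scored, thresholds) {
  m2f <- ifelse(scored$testable, scored$m2f, NA_real_)
  scored$call <- classify_m2f(m2f, thresholds)
  scored$supported_annotation <- ifelse(
    is.na(scored$call), NA_character_,
    ifelse(scored$call == "merge_supported", scored$merged_annotation,
           ifelse(scored$call == "split_supported", scored$split_annotation,
                  NA_character_)))
  scored$t_merge <- thresholds$t_merge
  scored$t_split <- thresholds$t_split
  scored
}

#' Cross-comparison consistency of calls
#'
#' For anchor genes with calls from exactly two independent pairwise
#' comparisons (a single gene corresponding to split genes in both alternate
#' annotations, or vice versa), statuses are: `consistent` (same call),
#' `conflict` (one merge_supported, one split_supported), `partial` (one
#' decisive, one ambiguous). Anchors with a different number of calls are
#' excluded with a warning.
#'
#' @param calls data.frame with columns `anchor_gene`, `comparison`, `call`,
#'   `m2f`.
#' @return list with `comparisons` (one row per anchor: both calls and M2f
#'   values, `status`) and `joint_table` (3 x 3 contingency table of the two
#'   calls).
#' @export
cross_compare <- function(calls) {
  lv <- c("merge_supported", "ambiguous", "split_supported")
  counts <- table(calls$anchor_gene)
  bad <- names(counts)[counts != 2L]
  if (length(bad)) {
    warning("excluding ", length(bad),
            " anchor gene(s) without exactly two calls")
    calls <- calls[!calls$anchor_gene %in% bad, , drop = FALSE]
  }
  calls <- calls[order(calls$anchor_gene, calls$comparison), , drop = FALSE]
  first <- calls[!duplicated(calls$anchor_gene), , drop = FALSE]
  second <- calls[duplicated(calls$anchor_gene), , drop = FALSE]
  stopifnot(identical(first$anchor_gene, second$anchor_gene))
  status <- ifelse(first$call == second$call, "consistent",
            ifelse((first$call == "merge_supported" & second$call == "split_supported") |
                   (first$call == "split_supported" & second$call == "merge_supported"),
                   "conflict", "partial"))
  comparisons <- data.frame(
    anchor_gene = first$anchor_gene,
    comparison_1 = first$comparison, call_1 = first$call, m2f_1 = first$m2f,
    comparison_2 = second$comparison, call_2 = second$call, m2f_2 = second$m2f,
    status = status, stringsAsFactors = FALSE)
  joint <- table(factor(comparisons$call_1, levels = lv),
                 factor(comparisons$call_2, levels = lv))
  list(comparisons = comparisons, joint_table = joint)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full split-gene pipeline on a pair of annotations
#'
#' Plumbing over the module functions: reads both annotations, the syntenic
#' blocks (reference side = annotation A), both BLAST directions, and exon
#' counts; computes expression, resolves reciprocal homology in both
#' directions, builds candidates (merged in A / split in B and merged in B /
#' split in A), scores M2f, simulates both nulls per split-side annotation,
#' derives pooled thresholds, and calls every testable candidate. Writes TSV
#' outputs and a run manifest of parameters and per-stage counts when
#' `out_dir` is set.
#'
#' @param gff_a,gff_b GFF3 paths.
#' @param genotype_a,genotype_b genotype labels (defaults: file names).
#' @param coords show-coords path, reference genome = annotation A.
#' @param blast_ab,blast_ba tabular BLAST paths (A transcripts vs B database,
#'   and the reciprocal).
#' @param counts_a,counts_b exon count TSVs (reads of each genotype mapped to
#'   its own annotation).
#' @param libraries library sheet TSV path or `library_sheet` object.
#' @param max_evalue,margin_bp,window,tandem_max homology parameters.
#' @param min_exon_len,floor,epsilon expression / M2f parameters.
#' @param null_cfg a [null_config()]; its `seed` (or the `seed` argument)
#'   makes the run reproducible.
#' @param seed integer seed (overrides `null_cfg$seed`).
#' @param out_dir optional output directory for TSVs and the manifest.
#' @return list with `annotations`, `candidates` (scored + called),
#'   `one_to_one`, `thresholds`, `nulls`, `manifest`.
#' @export
run_pipeline <- function(gff_a, gff_b, coords, blast_ab, blast_ba,
                         counts_a, counts_b, libraries,
                         genotype_a = NULL, genotype_b = NULL,
                         max_evalue = 1e-4, margin_bp = 500000, window = 5,
                         tandem_max = 0.1, min_exon_len = 50, floor = 0.01,
                         epsilon = 0.01, null_cfg = null_config(),
                         seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) null_cfg$seed <- seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ann_a <- stage("annotation", read_gff3(gff_a, genotype_a))
  ann_b <- stage("annotation", read_gff3(gff_b, genotype_b))
  libs <- stage("libraries",
                if (inherits(libraries, "library_sheet")) libraries
                else read_library_sheet(libraries))

  blocks <- stage("synteny", read_show_coords(coords))
  flip <- function(b) data.frame(ref_chrom = b$qry_chrom, ref_start = b$qry_start,
                                 ref_end = b$qry_end, qry_chrom = b$ref_chrom,
                                 qry_start = b$ref_start, qry_end = b$ref_end,
                                 orientation = b$orientation,
                                 stringsAsFactors = FALSE)
  tx_map <- c(transcript_map(ann_a), transcript_map(ann_b))
  hits_ab <- stage("blast", read_blast_tab(blast_ab, tx_map))
  hits_ba <- stage("blast", read_blast_tab(blast_ba, tx_map))

  hits_ab <- best_hits(hits_ab, max_evalue)
  hits_ab <- filter_by_synteny(hits_ab, blocks, ann_a, ann_b, margin_bp)
  hits_ba <- best_hits(hits_ba, max_evalue)
  hits_ba <- filter_by_synteny(hits_ba, flip(blocks), ann_b, ann_a, margin_bp)

  corr_ab <- classify_correspondences(hits_ab, ann_a, ann_b, window)
  corr_ba <- classify_correspondences(hits_ba, ann_b, ann_a, window)
  rec_ab <- reciprocal_resolve(corr_ab, corr_ba)   # merged in A, split in B
  rec_ba <- reciprocal_resolve(corr_ba, corr_ab)   # merged in B, split in A

  expr_stage <- function(path, ann) {
    m <- stage("expression", read_exon_counts(path, libs))
    m <- filter_short_exons(m, min_exon_len)
    et <- tpm(m)
    list(exon_tpm = et, gene = gene_expression(et, min_exon_len, floor))
  }
  ex_a <- expr_stage(counts_a, ann_a)
  ex_b <- expr_stage(counts_b, ann_b)
  expressed <- union(expressed_genes(ex_a$gene, floor),
                     expressed_genes(ex_b$gene, floor))

  cand_ab <- stage("candidates",
                   build_split_candidates(rec_ab$one_to_many, ann_a, ann_b,
                                          hits_ba, expressed, window, tandem_max))
  cand_ba <- stage("candidates",
                   build_split_candidates(rec_ba$one_to_many, ann_b, ann_a,
                                          hits_ab, expressed, window, tandem_max))
  candidates <- rbind(cand_ab, cand_ba)

  expr_by_gt <- setNames(list(ex_a$gene, ex_b$gene),
                         c(ann_a$genotype, ann_b$genotype))
  scored <- stage("m2f", m2f_table(candidates, expr_by_gt, epsilon))

  exclude <- unique(c(candidates$merged_gene,
                      unlist(split_gene_field(candidates$split_genes))))
  null_for <- function(ann, ex, offset) {
    cfg <- null_cfg
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + offset
    mc <- m2f_config(epsilon = epsilon, genotype = ann$genotype)
    list(split = simulate_split_null(ann, ex$exon_tpm, exclude, cfg, mc),
         merged = simulate_merged_null(ann, ex$gene, exclude, cfg, mc))
  }
  nulls_a <- stage("null_simulation", null_for(ann_a, ex_a, 1L))
  nulls_b <- stage("null_simulation", null_for(ann_b, ex_b, 2L))
  thresholds <- compute_thresholds(list(nulls_a$split, nulls_b$split),
                                   list(nulls_a$merged, nulls_b$merged),
                                   null_cfg, pool = TRUE)

  called <- call_candidates(scored, thresholds)

  manifest <- list(
    genotype_a = ann_a$genotype, genotype_b = ann_b$genotype,
    seed = null_cfg$seed,
    params = list(max_evalue = max_evalue, margin_bp = margin_bp,
                  window = window, tandem_max = tandem_max,
                  min_exon_len = min_exon_len, floor = floor,
                  epsilon = epsilon,
                  split_fraction = null_cfg$split_fraction,
                  merged_fraction = null_cfg$merged_fraction),
    counts = c(
      genes_a = nrow(ann_a$genes), genes_b = nrow(ann_b$genes),
      hits_ab = nrow(hits_ab), hits_ba = nrow(hits_ba),
      one_to_one_ab = nrow(rec_ab$one_to_one),
      one_to_many_ab = nrow(rec_ab$one_to_many),
      one_to_many_ba = nrow(rec_ba$one_to_many),
      candidates = nrow(called),
      testable = sum(called$testable),
      merge_supported = sum(called$call == "merge_supported", na.rm = TRUE),
      split_supported = sum(called$call == "split_supported", na.rm = TRUE),
      ambiguous = sum(called$call == "ambiguous", na.rm = TRUE)),
    thresholds = c(t_merge = thresholds$t_merge, t_split = thresholds$t_split)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(rec_ab$one_to_one, file.path(out_dir, "one_to_one.tsv"))
    write_tsv(called, file.path(out_dir, "calls.tsv"))
    write_tsv(data.frame(kind = "split_null", annotation = nulls_a$split$annotation,
                         m2f = nulls_a$split$values),
              file.path(out_dir, "null_split_a.tsv"))
    key_val <- data.frame(
      key = c(names(manifest$counts), names(manifest$thresholds), "seed"),
      value = c(manifest$counts, manifest$thresholds,
                if (is.null(manifest$seed)) NA else manifest$seed))
    write_tsv(key_val, file.path(out_dir, "manifest.tsv"))
  }

  list(annotations = list(a = ann_a, b = ann_b),
       one_to_one = rec_ab$one_to_one,
       candidates = called,
       thresholds = thresholds,
       nulls = list(a = nulls_a, b = nulls_b),
       manifest = manifest)
}
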