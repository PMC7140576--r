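#' Run the full method on an in-memory synthetic fixture
#'
#' Convenience harness for validation studies: runs the homology stages on the
#' fixture's hit tables, computes expression and M2f, simulates matched nulls
#' on both annotations (candidate genes excluded), derives pooled thresholds,
#' and calls every testable candidate. Candidates are joined with the
#' fixture's truth table.
#'
#' @param fixture an `sg_fixture` from [generate_annotation_pair()].
#' @param expr output of [generate_expression()] for the same fixture.
#' @param window,tandem_max,min_exon_len,floor,epsilon analysis parameters.
#' @param null_cfg a [null_config()]; defaults to seeding with
#'   `fixture$cfg$seed + 2`.
#' @return list with `candidates` (scored, called, truth-joined), `thresholds`,
#'   `nulls`, `one_to_one`, `expr_gene` (per-genotype `gene_expr`).
#' @export
analyze_fixture <- function(fixture, expr, window = 5, tandem_max = 0.1,
                            min_exon_len = 50, floor = 0.01, epsilon = 0.01,
                            null_cfg = NULL) {
  cfg <- fixture$cfg
  if (is.null(null_cfg)) null_cfg <- null_config(seed = cfg$seed + 2L)
  gts <- cfg$genotypes
  ann_a <- fixture$annotations[[gts[1]]]
  ann_b <- fixture$annotations[[gts[2]]]

  hits_ab <- filter_by_synteny(best_hits(fixture$hits_ab), fixture$blocks,
                               ann_a, ann_b)
  flip <- fixture$blocks
  names(flip) <- c("qry_chrom", "qry_start", "qry_end",
                   "ref_chrom", "ref_start", "ref_end", "orientation")
  hits_ba <- filter_by_synteny(best_hits(fixture$hits_ba), flip, ann_b, ann_a)

  corr_ab <- classify_correspondences(hits_ab, ann_a, ann_b, window)
  corr_ba <- classify_correspondences(hits_ba, ann_b, ann_a, window)
  rec_ab <- reciprocal_resolve(corr_ab, corr_ba)
  rec_ba <- reciprocal_resolve(corr_ba, corr_ab)

  expr_stage <- function(gt) {
    et <- tpm(filter_short_exons(expr$counts[[gt]], min_exon_len))
    list(exon_tpm = et, gene = gene_expression(et, min_exon_len, floor))
  }
  ex <- setNames(lapply(gts, expr_stage), gts)
  expressed <- unique(unlist(lapply(ex, function(e) expressed_genes(e$gene, floor))))

  cand_ab <- build_split_candidates(rec_ab$one_to_many, ann_a, ann_b, hits_ba,
                                    expressed, window, tandem_max)
  cand_ba <- build_split_candidates(rec_ba$one_to_many, ann_b, ann_a, hits_ab,
                                    expressed, window, tandem_max)
  candidates <- rbind(cand_ab, cand_ba)

  expr_gene <- setNames(lapply(gts, function(gt) ex[[gt]]$gene), gts)
  scored <- m2f_table(candidates, expr_gene, epsilon)

  exclude <- unique(c(candidates$merged_gene,
                      unlist(split_gene_field(candidates$split_genes))))
  nulls <- lapply(seq_along(gts), function(i) {
    gt <- gts[i]
    ncfg <- null_cfg
    if (!is.null(ncfg$seed)) ncfg$seed <- ncfg$seed + i
    mc <- m2f_config(epsilon = epsilon, genotype = gt)
    list(split = simulate_split_null(fixture$annotations[[gt]],
                                     ex[[gt]]$exon_tpm, exclude, ncfg, mc),
         merged = simulate_merged_null(fixture$annotations[[gt]],
                                       ex[[gt]]$gene, exclude, ncfg, mc))
  })
  thresholds <- compute_thresholds(lapply(nulls, `[[`, "split"),
                                   lapply(nulls, `[[`, "merged"),
                                   null_cfg, pool = TRUE)
  called <- call_candidates(scored, thresholds)

  truth <- fixture$truth
  idx <- match(called$merged_gene, truth$gene_a)
  called$truth_class <- truth$class[idx]
  called$expected_call <- truth$expected_call[idx]

  list(candidates = called, thresholds = thresholds, nulls = nulls,
       one_to_one = rec_ab$one_to_one, expr_gene = expr_gene)
}

#' Recovery rates of a fixture analysis
#'
#' Among testable candidates with a decisive (non-ambiguous) call, the fraction
#' whose call matches the fixture's expected call, per truth class.
#'
#' @param result output of [analyze_fixture()].
#' @return data.frame with one row per truth class: `n_testable`,
#'   `n_decisive`, `n_correct`, `rate`, `median_m2f`.
#' @export
recovery_rates <- function(result) {
  cand <- result$candidates
  cand <- cand[!is.na(cand$expected_call) & cand$testable, , drop = FALSE]
  out <- lapply(split(cand, cand$truth_class), function(x) {
    decisive <- x[!is.na(x$call) & x$call != "ambiguous", , drop = FALSE]
    data.frame(truth_class = x$truth_class[1],
               n_testable = nrow(x),
               n_decisive = nrow(decisive),
               n_correct = sum(decisive$call == decisive$expected_call),
               rate = if (nrow(decisive)) {
                 sum(decisive$call == decisive$expected_call) / nrow(decisive)
               } else NA_real_,
               median_m2f = median(x$m2f, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
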