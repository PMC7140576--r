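test_that("percentile follows the linear-interpolation convention", {
  expect_equal(percentile(1:10, 10), 1.9)
  expect_equal(percentile(1:10, 90), 9.1)
  expect_equal(percentile(10:1, 10), 1.9)          # order-free
  expect_equal(percentile(42, 37), 42)             # single value
  expect_error(percentile(numeric(0), 50), "empty")
  # agrees with the type-7 quantile definition on random data
  set.seed(9)
  for (rep in 1:10) {
    x <- rexp(sample(5:200, 1))
    p <- runif(1, 1, 99)
    expect_equal(percentile(x, p),
                 unname(quantile(x, p / 100, type = 7)))
  }
})

make_split_fixture <- function(seed = 1, sigma = 1.5, n_one = 30) {
  cfg <- fixture_config(n_one_to_one = n_one, n_true_split = 4,
                        n_tissues = 4, n_replicates = 2,
                        sigma = sigma, seed = seed)
  fx <- generate_annotation_pair(cfg)
  ex <- generate_expression(fx)
  list(cfg = cfg, fx = fx, ex = ex)
}

test_that("split null samples eligible genes and splits at valid junctions", {
  f <- make_split_fixture()
  ann <- f$fx$annotations$GB
  et <- tpm(filter_short_exons(f$ex$counts$GB))
  exclude <- unlist(strsplit(f$fx$truth$genes_b[f$fx$truth$class != "one_to_one"], ","))
  nd <- simulate_split_null(ann, et, exclude, null_config(seed = 5),
                            m2f_config(genotype = "GB"))
  eligible <- ann$genes$gene_id[ann$genes$n_exons >= 4]
  eligible <- setdiff(eligible, exclude)
  expect_equal(nd$n, floor(0.2 * length(eligible)))
  expect_length(nd$values, nd$n)
  expect_true(all(nd$genes %in% eligible))
  expect_false(any(duplicated(nd$genes)))       # without replacement
  expect_true(all(nd$values >= 0))
  # determinism under the seed
  nd2 <- simulate_split_null(ann, et, exclude, null_config(seed = 5),
                             m2f_config(genotype = "GB"))
  expect_identical(nd$values, nd2$values)
  expect_identical(nd$genes, nd2$genes)
})

test_that("a 4-exon gene is split only at the middle junction", {
  # single gene, 4 exons with distinct TPM: halves must be exons {1,2} | {3,4}
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 0, end = 4000, cds_length = 400,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", start = c(0, 1000, 2000, 3000),
                      end = c(100, 1100, 2100, 3100), stringsAsFactors = FALSE)
  ann <- annotation("X", genes, exons)
  tpm_vals <- matrix(c(100, 200, 400, 800), nrow = 4,
                     dimnames = list(paste0("g1:", 1:4), "L01"))
  et <- structure(list(values = tpm_vals,
                       exons = data.frame(exon_id = rownames(tpm_vals),
                                          gene_id = "g1", length = 100),
                       libraries = library_sheet("L01", "X", "T01", 1L),
                       dropped_genes = character(0)), class = "exon_tpm")
  cfg <- null_config(split_fraction = 1, seed = 2)
  nd <- simulate_split_null(ann, et, character(0), cfg, m2f_config(epsilon = 0))
  expect_equal(nd$values, abs(log2(mean(c(100, 200)) / mean(c(400, 800)))))
  # a 3-exon gene is ineligible
  ann3 <- annotation("X", genes,
                     data.frame(gene_id = "g1", start = c(0, 1000, 2000),
                                end = c(100, 1100, 2100)))
  et3 <- et
  et3$values <- tpm_vals[1:3, , drop = FALSE]
  et3$exons <- et$exons[1:3, ]
  expect_error(simulate_split_null(ann3, et3, character(0), cfg), "eligible")
})

test_that("merged null pairs each anchor with its upstream rank neighbor", {
  f <- make_split_fixture()
  ann <- f$fx$annotations$GB
  ge <- gene_expression(tpm(filter_short_exons(f$ex$counts$GB)))
  exclude <- unlist(strsplit(f$fx$truth$genes_b[f$fx$truth$class != "one_to_one"], ","))
  nd <- simulate_merged_null(ann, ge, exclude, null_config(seed = 6),
                             m2f_config(genotype = "GB"))
  expect_gt(nd$n, 0)
  expect_false(any(duplicated(nd$genes$anchor)))
  g <- ann$genes
  for (i in seq_len(nd$n)) {
    a <- nd$genes$anchor[i]; p <- nd$genes$partner[i]
    expect_equal(g[a, "chrom"], g[p, "chrom"])
    expect_equal(g[a, "rank"] - 1L, g[p, "rank"])   # adjacent upstream
  }
  expect_length(intersect(c(nd$genes$anchor, nd$genes$partner), exclude), 0)
  nd2 <- simulate_merged_null(ann, ge, exclude, null_config(seed = 6),
                              m2f_config(genotype = "GB"))
  expect_identical(nd$values, nd2$values)
})

test_that("rank-0 genes are never anchors (no upstream neighbor)", {
  f <- make_split_fixture()
  ann <- f$fx$annotations$GB
  ge <- gene_expression(tpm(filter_short_exons(f$ex$counts$GB)))
  nd <- simulate_merged_null(ann, ge, character(0),
                             null_config(merged_fraction = 1, seed = 1),
                             m2f_config(genotype = "GB"))
  rank0 <- ann$genes$gene_id[ann$genes$rank == 0L]
  expect_false(any(nd$genes$anchor %in% rank0))
})

test_that("thresholds are the stated percentiles, pooled by concatenation", {
  d1 <- splitgenes:::new_null_distribution("split_null", 1:10, "A", 1, 10)
  d2 <- splitgenes:::new_null_distribution("split_null", 11:20, "B", 1, 10)
  m1 <- splitgenes:::new_null_distribution("merged_null", seq(2, 20, 2), "A", 1, 10)
  th <- suppressWarnings(compute_thresholds(d1, m1))
  expect_equal(th$t_split, percentile(1:10, 90))
  expect_equal(th$t_merge, percentile(seq(2, 20, 2), 10))
  th2 <- suppressWarnings(compute_thresholds(list(d1, d2), list(m1, m1)))
  expect_equal(th2$t_split, percentile(1:20, 90))
  expect_equal(th2$n_split, 20L)
  th3 <- suppressWarnings(compute_thresholds(list(d1, d2), list(m1, m1), pool = FALSE))
  expect_equal(th3$per_annotation[[2]]$t_split, percentile(11:20, 90))
  m_hi <- splitgenes:::new_null_distribution("merged_null", 100:110, "A", 1, 11)
  expect_warning(compute_thresholds(d1, m_hi), "t_merge")
})

test_that("on divergent synthetic data the merged null sits above the split null", {
  f <- make_split_fixture(seed = 13, sigma = 1.5, n_one = 60)
  ann <- f$fx$annotations$GB
  ec <- filter_short_exons(f$ex$counts$GB)
  et <- tpm(ec)
  ge <- gene_expression(et)
  exclude <- unlist(strsplit(f$fx$truth$genes_b[f$fx$truth$class != "one_to_one"], ","))
  mc <- m2f_config(genotype = "GB")
  nd_s <- simulate_split_null(ann, et, exclude, null_config(seed = 8), mc)
  nd_m <- simulate_merged_null(ann, ge, exclude, null_config(seed = 8), mc)
  expect_gt(median(nd_m$values), median(nd_s$values))
})
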