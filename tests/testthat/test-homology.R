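test_that("best_hits keeps the minimal e-value, breaking ties by length", {
  hits <- rbind(
    make_hits("q1", "s1", evalue = 1e-5, sstart = 0, send = 100),
    make_hits("q1", "s1", evalue = 1e-10, sstart = 0, send = 80),
    make_hits("q2", "s1", evalue = 1e-20, sstart = 0, send = 200),
    make_hits("q2", "s1", evalue = 1e-20, sstart = 0, send = 150)
  )
  out <- best_hits(hits)
  expect_equal(nrow(out), 2L)
  expect_equal(out$evalue[out$query_gene == "q1"], 1e-10)
  expect_equal(out$match_length[out$query_gene == "q2"], 200L)
})

test_that("best_hits applies a strict e-value cutoff", {
  hits <- rbind(make_hits("q1", "s1", evalue = 1e-3),
                make_hits("q2", "s1", evalue = 1e-4),
                make_hits("q3", "s1", evalue = 0.99e-4))
  out <- best_hits(hits, max_evalue = 1e-4)
  expect_equal(out$query_gene, "q3")   # 1e-3 and exactly 1e-4 both removed
})

test_that("best_hits is idempotent on random hit tables", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 200
    hits <- make_hits(sample(paste0("q", 1:20), n, TRUE),
                      sample(paste0("s", 1:20), n, TRUE),
                      evalue = 10^-runif(n, 0, 50),
                      sstart = 0, send = sample(50:500, n, TRUE))
    once <- best_hits(hits)
    expect_identical(best_hits(once), once)
    expect_true(all(!duplicated(once[, c("query_gene", "subject_gene")])))
  }
})

test_that("filter_by_synteny keeps hits within the margin-extended block", {
  # one block: ref [1.0, 2.0) Mb, qry [1.0, 2.0) Mb on chr1
  blocks <- data.frame(ref_chrom = "chr1", ref_start = 1e6, ref_end = 2e6,
                       qry_chrom = "chr1", qry_start = 1e6, qry_end = 2e6,
                       orientation = "same", stringsAsFactors = FALSE)
  mk_ann <- function(gt, starts) {
    genes <- data.frame(gene_id = paste0(gt, "_g", seq_along(starts)),
                        chrom = "chr1", strand = "+",
                        start = starts, end = starts + 10000,
                        cds_length = 500, stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = genes$gene_id, start = starts,
                        end = starts + 500, stringsAsFactors = FALSE)
    annotation(gt, genes, exons)
  }
  qa <- mk_ann("A", c(2.3e6, 2.6e6))   # 300 kb and 600 kb past the block end
  sa <- mk_ann("B", 1.5e6)
  hits <- rbind(make_hits("A_g1", "B_g1"), make_hits("A_g2", "B_g1"))
  out <- filter_by_synteny(hits, blocks, qa, sa, margin_bp = 500000)
  expect_equal(out$query_gene, "A_g1")  # within +500 kb; 600 kb is out

  # chromosome with no blocks: everything removed
  blocks2 <- blocks; blocks2$ref_chrom <- "chr9"
  expect_equal(nrow(filter_by_synteny(hits, blocks2, qa, sa)), 0L)
})

test_that("correspondences are classified by subject count and rank proximity", {
  qa <- spaced_annotation(3, "A")
  sa <- spaced_annotation(45, "B")   # ranks 0..44 by construction
  hits <- rbind(
    make_hits("A_g001", "B_g011"),                      # single (rank 10)
    make_hits("A_g002", c("B_g011", "B_g013")),         # ranks 10, 12
    make_hits("A_g003", c("B_g011", "B_g041"))          # ranks 10, 40
  )
  corr <- classify_correspondences(hits, qa, sa, window = 5)
  corr <- corr[match(paste0("A_g00", 1:3), corr$query_gene), ]
  expect_equal(corr$classification, c("single", "multiple", "multiple"))
  expect_equal(corr$proximal, c(TRUE, TRUE, FALSE))
  # a query gene with no surviving hits is classified 'none'
  corr0 <- classify_correspondences(hits[0, ], qa, sa)
  expect_true(all(corr0$classification == "none"))
  expect_equal(nrow(corr0), 3L)
})

test_that("reciprocal_resolve confirms symmetric and exclusive relations", {
  qa <- spaced_annotation(3, "A")
  sa <- spaced_annotation(4, "B")
  # g1 <-> h1 one-to-one; g2 -> {h2,h3} exclusive; g3 -> {h3?, h4} violated
  a2b <- classify_correspondences(rbind(
    make_hits("A_g001", "B_g001"),
    make_hits("A_g002", c("B_g002", "B_g003")),
    make_hits("A_g003", "B_g004")
  ), qa, sa)
  b2a <- classify_correspondences(rbind(
    make_hits("B_g001", "A_g001"),
    make_hits("B_g002", "A_g002"),
    make_hits("B_g003", c("A_g002", "A_g003")),   # h3 not exclusive
    make_hits("B_g004", "A_g001")                 # h4 points elsewhere
  ), sa, qa)
  expect_message(rec <- reciprocal_resolve(a2b, b2a), "non-exclusive")
  expect_equal(rec$one_to_one, data.frame(gene_a = "A_g001", gene_b = "B_g001",
                                          stringsAsFactors = FALSE))
  expect_equal(nrow(rec$one_to_many), 0L)  # h3's multiple classification breaks exclusivity

  # clean exclusive case
  b2a2 <- classify_correspondences(rbind(
    make_hits("B_g001", "A_g001"),
    make_hits("B_g002", "A_g002"),
    make_hits("B_g003", "A_g002")
  ), sa, qa)
  rec2 <- reciprocal_resolve(a2b, b2a2)
  expect_equal(rec2$one_to_many$single_gene, "A_g002")
  expect_equal(rec2$one_to_many$many_genes, "B_g002,B_g003")
  # disjointness: no gene in both outputs
  flat_many <- unlist(strsplit(rec2$one_to_many$many_genes, ","))
  expect_length(intersect(c(rec2$one_to_one$gene_a, rec2$one_to_one$gene_b),
                          c(rec2$one_to_many$single_gene, flat_many)), 0)
})

test_that("tandem_ratio measures multi-query overlap of aligned subject space", {
  # disjoint alignments: L1 = 0, L2 = 800
  h <- rbind(make_hits("q1", "s", sstart = 100, send = 500),
             make_hits("q2", "s", sstart = 500, send = 900))
  expect_equal(tandem_ratio(h), 0)
  # [100,600) and [400,1000): overlap 200, union 900
  h2 <- rbind(make_hits("q1", "s", sstart = 100, send = 600),
              make_hits("q2", "s", sstart = 400, send = 1000))
  expect_equal(tandem_ratio(h2), 200 / 900)
  # identical intervals: ratio 1
  h3 <- rbind(make_hits("q1", "s", sstart = 0, send = 300),
              make_hits("q2", "s", sstart = 0, send = 300))
  expect_equal(tandem_ratio(h3), 1)
})

test_that("tandem_ratio is translation invariant and bounded", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    s <- sort(sample(0:5000, k))
    w <- sample(100:800, k, replace = TRUE)
    h <- make_hits(paste0("q", seq_len(k)), rep("s", k), sstart = s, send = s + w)
    r <- tandem_ratio(h)
    expect_gte(r, 0); expect_lte(r, 1)
    shift <- sample(1:10000, 1)
    h2 <- h; h2$sstart <- h2$sstart + shift; h2$send <- h2$send + shift
    expect_equal(tandem_ratio(h2), r)
  }
})

test_that("candidacy filters flag strand, overlap, tandem, expression, proximity", {
  sa <- spaced_annotation(8, "B", strand = c("+", "+", "+", "-", "+", "+", "+", "+"))
  ma <- spaced_annotation(4, "A")
  one2many <- data.frame(
    single_gene = c("A_g001", "A_g002", "A_g003"),
    many_genes = c("B_g001,B_g002", "B_g003,B_g004", "B_g005,B_g006"),
    n_many = 2L, stringsAsFactors = FALSE)
  hits <- rbind(
    make_hits("B_g001", "A_g001", sstart = 0, send = 500),
    make_hits("B_g002", "A_g001", sstart = 500, send = 1000),
    make_hits("B_g003", "A_g002", sstart = 0, send = 500),
    make_hits("B_g004", "A_g002", sstart = 500, send = 1000),
    # exactly 10% multi-covered: union 900, overlap [410,500) = 90
    make_hits("B_g005", "A_g003", sstart = 0, send = 500),
    make_hits("B_g006", "A_g003", sstart = 410, send = 900))
  expressed <- c("A_g001", "A_g002", "A_g003", "B_g001", "B_g002",
                 "B_g003", "B_g004", "B_g005")  # B_g006 unexpressed
  cand <- build_split_candidates(one2many, ma, sa, hits, expressed)
  rownames(cand) <- cand$merged_gene
  expect_true(cand["A_g001", "testable"])
  expect_false(cand["A_g002", "strand_pass"])    # B_g004 is on '-'
  expect_equal(cand["A_g003", "tandem_ratio"], 0.1)
  expect_false(cand["A_g003", "tandem_pass"])    # 0.1 excluded: strict < 0.1
  expect_false(cand["A_g003", "expressed_pass"]) # B_g006 below the floor
  expect_error(build_split_candidates(
    data.frame(single_gene = "A_g001", many_genes = "B_g001,NOPE", n_many = 2L),
    ma, sa, hits, expressed), "NOPE")
})

test_that("overlapping split genes fail the overlap filter", {
  genes <- data.frame(gene_id = c("B_g1", "B_g2"), chrom = "chr1", strand = "+",
                      start = c(1000, 1500), end = c(2000, 2600),
                      cds_length = 400, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("B_g1", "B_g2"), start = c(1000, 1500),
                      end = c(1400, 1900), stringsAsFactors = FALSE)
  sa <- annotation("B", genes, exons)
  ma <- spaced_annotation(1, "A")
  hits <- rbind(make_hits("B_g1", "A_g001", sstart = 0, send = 400),
                make_hits("B_g2", "A_g001", sstart = 400, send = 800))
  cand <- build_split_candidates(
    data.frame(single_gene = "A_g001", many_genes = "B_g1,B_g2", n_many = 2L),
    ma, sa, hits, expressed = c("A_g001", "B_g1", "B_g2"))
  expect_false(cand$overlap_pass)
  expect_false(cand$testable)
  expect_true(cand$strand_pass && cand$tandem_pass && cand$expressed_pass)
})

test_that("corroborate marks relations seen in both comparisons", {
  base <- function(merged_ann, merged, split_ann, splits) {
    data.frame(merged_annotation = merged_ann, merged_gene = merged,
               split_annotation = split_ann, split_genes = splits,
               n_split = 2L, tandem_ratio = 0, overlap_pass = TRUE,
               strand_pass = TRUE, tandem_pass = TRUE, expressed_pass = TRUE,
               proximal_pass = TRUE, testable = TRUE,
               candidate_id = paste0(merged, "|", splits),
               corroboration = "unset", stringsAsFactors = FALSE)
  }
  ab <- rbind(base("A", "a1", "B", "b1,b2"),    # a1 merged vs B
              base("B", "b9", "A", "a5,a6"))    # A split pair vs B single
  ac <- rbind(base("A", "a1", "C", "c1,c2"),    # a1 merged vs C too
              base("C", "c9", "A", "a5,a6"),    # same A pair vs C single
              base("A", "a2", "C", "c3,c4"))
  out <- corroborate(ab, ac)
  expect_equal(out$candidates_ab$corroboration, c("corroborated", "corroborated"))
  expect_equal(out$candidates_ac$corroboration,
               c("corroborated", "corroborated", "unique"))
  # empty second list: everything unique
  out2 <- corroborate(ab, ac[0, ], label_a = "A")
  expect_true(all(out2$candidates_ab$corroboration == "unique"))
})
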