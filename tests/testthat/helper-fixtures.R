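# Shared builders for hand-sized test objects. Everything is constructed in
# code; no fixture files are stored.

# n genes evenly spaced on one chromosome: gene i spans [i*10000, i*10000+1000)
# with two 300 bp exons; rank i-1.
spaced_annotation <- function(n, genotype = "X", chrom = "chr1", strand = NULL) {
  if (is.null(strand)) strand <- rep("+", n)
  start <- (seq_len(n)) * 10000
  genes <- data.frame(gene_id = sprintf("%s_g%03d", genotype, seq_len(n)),
                      chrom = chrom, strand = strand,
                      start = start, end = start + 1000,
                      cds_length = 600,
                      transcript_id = sprintf("%s_g%03d_T01", genotype, seq_len(n)),
                      stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(gene_id = genes$gene_id, start = start, end = start + 300,
               stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, start = start + 600, end = start + 900,
               stringsAsFactors = FALSE))
  annotation(genotype, genes, exons)
}

make_hits <- function(query_gene, subject_gene, evalue = 1e-50,
                      sstart = 0, send = 500) {
  data.frame(query_gene = query_gene, subject_gene = subject_gene,
             evalue = evalue, match_length = as.integer(send - sstart),
             sstart = sstart, send = send, stringsAsFactors = FALSE)
}

# small exon count object: counts is exons x libraries, lengths per exon
make_counts <- function(counts, lengths, gene_ids, lib_genotype = "X") {
  n_lib <- ncol(counts)
  libs <- library_sheet(sprintf("L%02d", seq_len(n_lib)),
                        rep(lib_genotype, n_lib),
                        sprintf("T%02d", seq_len(n_lib)),
                        rep(1L, n_lib))
  exons <- data.frame(exon_id = sprintf("e%03d", seq_len(nrow(counts))),
                      gene_id = gene_ids, length = lengths,
                      stringsAsFactors = FALSE)
  colnames(counts) <- libs$library_id
  rownames(counts) <- exons$exon_id
  exon_counts(counts, exons, libs)
}

# gene_expr object directly from a genes x libraries matrix
make_gene_expr <- function(values, genotypes = NULL) {
  n_lib <- ncol(values)
  if (is.null(genotypes)) genotypes <- rep("X", n_lib)
  libs <- library_sheet(colnames(values), genotypes,
                        sprintf("T%02d", seq_len(n_lib)), rep(1L, n_lib))
  structure(list(values = values, libraries = libs,
                 config = list(min_exon_len = 50, floor = 0.01),
                 missing_genes = character(0)),
            class = "gene_expr")
}

# naive reference implementation of M2f: explicit triple loop over libraries,
# gene pairs, and terms; independent of the production matrix code path
naive_m2f <- function(vals, epsilon) {
  per_lib <- numeric(ncol(vals))
  for (l in seq_len(ncol(vals))) {
    acc <- c()
    for (i in seq_len(nrow(vals) - 1)) {
      for (j in (i + 1):nrow(vals)) {
        a <- vals[i, l] + epsilon
        b <- vals[j, l] + epsilon
        acc <- c(acc, abs(log2(a / b)))
      }
    }
    per_lib[l] <- mean(acc)
  }
  mean(per_lib)
}

# GFF3 text for a configurable two-transcript gene, used by the reader tests
write_toy_gff3 <- function(path, cds2_len = 450, tx_ids = c("t1", "t2")) {
  lines <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t2000\t.\t+\t.\tID=g1",
    sprintf("chr1\tsrc\tmRNA\t101\t2000\t.\t+\t.\tID=%s;Parent=g1", tx_ids[1]),
    sprintf("chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=%s.e1;Parent=%s", tx_ids[1], tx_ids[1]),
    sprintf("chr1\tsrc\texon\t301\t500\t.\t+\t.\tID=%s.e2;Parent=%s", tx_ids[1], tx_ids[1]),
    sprintf("chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tID=%s.c1;Parent=%s", tx_ids[1], tx_ids[1]),
    sprintf("chr1\tsrc\tCDS\t301\t500\t.\t+\t0\tID=%s.c2;Parent=%s", tx_ids[1], tx_ids[1]),
    sprintf("chr1\tsrc\tmRNA\t101\t2000\t.\t+\t.\tID=%s;Parent=g1", tx_ids[2]),
    sprintf("chr1\tsrc\texon\t101\t250\t.\t+\t.\tID=%s.e1;Parent=%s", tx_ids[2], tx_ids[2]),
    sprintf("chr1\tsrc\texon\t401\t900\t.\t+\t.\tID=%s.e2;Parent=%s", tx_ids[2], tx_ids[2]),
    sprintf("chr1\tsrc\tCDS\t101\t%d\t.\t+\t0\tID=%s.c1;Parent=%s",
            100 + cds2_len, tx_ids[2], tx_ids[2])
  )
  writeLines(lines, path)
  path
}

# standard small fixture config used by several suites
toy_fixture_config <- function(seed = 42) {
  fixture_config(n_one_to_one = 10, n_tandem = 2, n_true_split = 3,
                 n_strand_fail = 1, n_overlap_fail = 1,
                 n_tissues = 4, n_replicates = 2, seed = seed)
}
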