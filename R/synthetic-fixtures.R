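#' Synthetic-fixture configuration
#'
#' Controls the generator that fabricates a pair of annotations with known
#' ground truth plus the matching alignment tables and exon counts, so every
#' pipeline stage can be exercised without external data.
#'
#' Case classes (per locus, annotation A vs annotation B):
#' \describe{
#'   \item{one_to_one}{the same gene in both annotations.}
#'   \item{true_merged}{one true gene; B misannotates it as two adjacent genes.
#'     Both B genes share one expression profile; the expected call is
#'     merge_supported.}
#'   \item{true_split}{two true genes; A misannotates them as one merged gene.
#'     The B genes' profiles diverge by per-tissue effects of sd `sigma`; the
#'     expected call is split_supported.}
#'   \item{tandem}{two B duplicates whose alignments overlap the same region of
#'     the A gene (L1/L2 >= 0.1); excluded by the tandem filter.}
#'   \item{strand_fail / overlap_fail}{candidate geometry violating the strand
#'     / non-overlap filters.}
#' }
#'
#' @param n_one_to_one,n_tandem,n_true_split,n_true_merged,n_strand_fail,n_overlap_fail
#'   case counts per class.
#' @param n_tissues,n_replicates libraries per genotype = tissues x replicates
#'   (defaults 10 and 2, two biological replicates per genotype/tissue).
#' @param exons_per_gene integer range of exon counts for single-unit genes
#'   (default 4..8; split parts get roughly half each, at least 2).
#' @param exon_len_range,intron_len_range exon / intron lengths in bp.
#' @param mean_log2_tpm baseline log2 expression rate shared by all genes.
#' @param nb_dispersion negative-binomial dispersion of counts (default 0.1).
#' @param sigma sd (log2 units) of the independent per-tissue expression
#'   effects that separate DISTINCT genes; genes of one true unit share their
#'   profile, and any two distinct genes differ per tissue by N(0, sigma^2).
#' @param genotypes two genotype labels.
#' @param seed integer seed; the whole fixture is deterministic given it.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n_one_to_one = 10, n_tandem = 0, n_true_split = 0,
                           n_true_merged = 0, n_strand_fail = 0,
                           n_overlap_fail = 0, n_tissues = 10,
                           n_replicates = 2, exons_per_gene = c(4, 8),
                           exon_len_range = c(80, 300),
                           intron_len_range = c(100, 400),
                           mean_log2_tpm = 5, nb_dispersion = 0.1,
                           sigma = 1.5, genotypes = c("GA", "GB"), seed = 1) {
  counts <- c(n_one_to_one, n_tandem, n_true_split, n_true_merged,
              n_strand_fail, n_overlap_fail)
  stopifnot(all(counts >= 0), sum(counts) > 0, n_tissues >= 1,
            n_replicates >= 1, nb_dispersion > 0, sigma >= 0,
            exons_per_gene[1] >= 4, length(genotypes) == 2)
  if (exon_len_range[1] < 1 || intron_len_range[1] < 1) {
    stop("exon and intron lengths must be >= 1 bp")
  }
  structure(list(n_one_to_one = n_one_to_one, n_tandem = n_tandem,
                 n_true_split = n_true_split, n_true_merged = n_true_merged,
                 n_strand_fail = n_strand_fail, n_overlap_fail = n_overlap_fail,
                 n_tissues = n_tissues, n_replicates = n_replicates,
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len_range = as.integer(exon_len_range),
                 intron_len_range = as.integer(intron_len_range),
                 mean_log2_tpm = mean_log2_tpm, nb_dispersion = nb_dispersion,
                 sigma = sigma, genotypes = genotypes, seed = as.integer(seed)),
            class = "fixture_config")
}

# lay one gene's exons down from `cursor`; returns gene/exon rows and geometry
make_part <- function(gene_id, tx_id, chrom, strand, cursor, exon_lens,
                      intron_lens) {
  n <- length(exon_lens)
  starts <- numeric(n); ends <- numeric(n)
  pos <- cursor
  for (j in seq_len(n)) {
    starts[j] <- pos
    ends[j] <- pos + exon_lens[j]
    pos <- ends[j] + if (j < n) intron_lens[j] else 0
  }
  list(
    gene = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      start = starts[1], end = ends[n],
                      cds_length = sum(exon_lens), transcript_id = tx_id,
                      stringsAsFactors = FALSE),
    exons = data.frame(gene_id = gene_id, start = starts, end = ends,
                       stringsAsFactors = FALSE),
    tlen = sum(exon_lens), end = ends[n]
  )
}

blast_row <- function(q, s, evalue, sstart0, send0) {
  data.frame(query_gene = q, subject_gene = s, evalue = evalue,
             match_length = as.integer(send0 - sstart0),
             sstart = sstart0, send = send0, stringsAsFactors = FALSE)
}

#' Generate a paired-annotation fixture with known truth
#'
#' Builds two annotations on one chromosome, the BLAST-like hit tables in both
#' directions, a single whole-chromosome syntenic block, a truth table, and the
#' exon-to-source-gene map that [generate_expression()] uses. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [fixture_config()].
#' @return list of class `sg_fixture` with components `cfg`, `annotations`
#'   (named by genotype), `hits_ab`, `hits_ba` (gene-keyed), `blocks`, `truth`,
#'   `exon_sources` (named vector: exon_id -> source gene).
#' @export
generate_annotation_pair <- function(cfg) {
  set.seed(cfg$seed)
  classes <- rep(c("one_to_one", "tandem", "true_split", "true_merged",
                   "strand_fail", "overlap_fail"),
                 times = c(cfg$n_one_to_one, cfg$n_tandem, cfg$n_true_split,
                           cfg$n_true_merged, cfg$n_strand_fail,
                           cfg$n_overlap_fail))
  classes <- sample(classes)
  n_case <- length(classes)
  chrom <- "chr1"

  ga <- list(); ea <- list(); gb <- list(); eb <- list()
  hab <- list(); hba <- list(); truth <- list()
  src_map <- character(0)

  rint <- function(rng, n = 1L) {
    if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n, replace = TRUE)
  }
  part_exon_range <- c(max(2L, floor(cfg$exons_per_gene[1] / 2)),
                       max(2L, ceiling(cfg$exons_per_gene[2] / 2)))
  cursor <- 10000
  na_ct <- 0L; nb_ct <- 0L; src_ct <- 0L

  new_src <- function() { src_ct <<- src_ct + 1L; sprintf("src%04d", src_ct) }
  a_id <- function() { na_ct <<- na_ct + 1L; sprintf("AG%04d", na_ct) }
  b_id <- function() { nb_ct <<- nb_ct + 1L; sprintf("BG%04d", nb_ct) }
  add_src <- function(gene_id, n_ex, src) {
    src_map[paste0(gene_id, ":", seq_len(n_ex))] <<- src
  }

  for (i in seq_len(n_case)) {
    cls <- classes[i]
    cursor <- cursor + rint(c(2000L, 8000L))
    if (cls == "one_to_one") {
      n_ex <- rint(cfg$exons_per_gene)
      el <- rint(cfg$exon_len_range, n_ex)
      il <- rint(cfg$intron_len_range, max(n_ex - 1L, 1L))
      idA <- a_id(); idB <- b_id(); src <- new_src()
      pA <- make_part(idA, paste0(idA, "_T001"), chrom, "+", cursor, el, il)
      pB <- make_part(idB, paste0(idB, "_T001"), chrom, "+", cursor, el, il)
      ga[[length(ga) + 1L]] <- pA$gene; ea[[length(ea) + 1L]] <- pA$exons
      gb[[length(gb) + 1L]] <- pB$gene; eb[[length(eb) + 1L]] <- pB$exons
      hab[[length(hab) + 1L]] <- blast_row(idA, idB, 1e-80, 0, pB$tlen)
      hba[[length(hba) + 1L]] <- blast_row(idB, idA, 1e-80, 0, pA$tlen)
      add_src(idA, n_ex, src); add_src(idB, n_ex, src)
      truth[[length(truth) + 1L]] <- data.frame(
        case_id = sprintf("case%04d", i), class = cls, gene_a = idA,
        genes_b = idB, expected_testable = NA, expected_call = NA_character_,
        stringsAsFactors = FALSE)
      cursor <- pA$end
      next
    }

    # two-part locus: B genes b1, b2; A single gene across the locus
    n1 <- rint(part_exon_range); n2 <- rint(part_exon_range)
    el1 <- rint(cfg$exon_len_range, n1); il1 <- rint(cfg$intron_len_range, max(n1 - 1L, 1L))
    el2 <- rint(cfg$exon_len_range, n2); il2 <- rint(cfg$intron_len_range, max(n2 - 1L, 1L))
    idA <- a_id(); id1 <- b_id(); id2 <- b_id()
    strand2 <- if (cls == "strand_fail") "-" else "+"

    p1 <- make_part(id1, paste0(id1, "_T001"), chrom, "+", cursor, el1, il1)
    start2 <- if (cls == "overlap_fail") {
      max(p1$gene$start + 1, p1$end - (el2[1] %/% 2))  # spans overlap
    } else {
      p1$end + rint(c(300L, 800L))
    }
    p2 <- make_part(id2, paste0(id2, "_T001"), chrom, strand2, start2, el2, il2)

    gb[[length(gb) + 1L]] <- p1$gene; eb[[length(eb) + 1L]] <- p1$exons
    gb[[length(gb) + 1L]] <- p2$gene; eb[[length(eb) + 1L]] <- p2$exons

    if (cls == "tandem") {
      # A gene mirrors part 1 only; the two B duplicates both align onto it,
      # overlapping on its transcript
      pA <- make_part(idA, paste0(idA, "_T001"), chrom, "+", cursor, el1, il1)
      ga[[length(ga) + 1L]] <- pA$gene; ea[[length(ea) + 1L]] <- pA$exons
      src1 <- new_src(); src2 <- new_src()
      add_src(idA, n1, src1); add_src(id1, n1, src1); add_src(id2, n2, src2)
      hab[[length(hab) + 1L]] <- blast_row(idA, id1, 1e-80, 0, p1$tlen)
      hab[[length(hab) + 1L]] <- blast_row(idA, id2, 1e-70, 0, p2$tlen)
      half <- floor(pA$tlen / 2)
      hba[[length(hba) + 1L]] <- blast_row(id1, idA, 1e-80, 0, pA$tlen)
      hba[[length(hba) + 1L]] <- blast_row(id2, idA, 1e-70, half, pA$tlen)
      end_case <- max(p1$end, p2$end, pA$end)
    } else {
      # A merged gene: the two parts' exon structures laid out consecutively
      # (A and B are distinct assemblies, so A's coordinates are independent
      # of B's overlapping geometry)
      pA1 <- make_part(idA, paste0(idA, "_T001"), chrom, "+", cursor, el1, il1)
      pA2 <- make_part(idA, paste0(idA, "_T001"), chrom, "+",
                       pA1$end + rint(c(300L, 800L)), el2, il2)
      exA <- rbind(pA1$exons, pA2$exons)
      gA <- data.frame(gene_id = idA, chrom = chrom, strand = "+",
                       start = min(exA$start), end = max(exA$end),
                       cds_length = sum(exA$end - exA$start),
                       transcript_id = paste0(idA, "_T001"),
                       stringsAsFactors = FALSE)
      ga[[length(ga) + 1L]] <- gA; ea[[length(ea) + 1L]] <- exA
      if (cls == "true_merged") {
        src1 <- new_src(); src2 <- src1
      } else {
        src1 <- new_src(); src2 <- new_src()
      }
      src_map[paste0(idA, ":", seq_len(n1 + n2))] <- c(rep(src1, n1), rep(src2, n2))
      add_src(id1, n1, src1); add_src(id2, n2, src2)
      hab[[length(hab) + 1L]] <- blast_row(idA, id1, 1e-80, 0, p1$tlen)
      hab[[length(hab) + 1L]] <- blast_row(idA, id2, 1e-70, 0, p2$tlen)
      # disjoint alignment on the merged transcript: tandem ratio 0
      hba[[length(hba) + 1L]] <- blast_row(id1, idA, 1e-80, 0, p1$tlen)
      hba[[length(hba) + 1L]] <- blast_row(id2, idA, 1e-70, p1$tlen, p1$tlen + p2$tlen)
      end_case <- max(p1$end, p2$end, pA2$end)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      case_id = sprintf("case%04d", i), class = cls, gene_a = idA,
      genes_b = paste(id1, id2, sep = ","),
      expected_testable = cls %in% c("true_split", "true_merged"),
      expected_call = switch(cls, true_split = "split_supported",
                             true_merged = "merge_supported", NA_character_),
      stringsAsFactors = FALSE)
    cursor <- end_case
  }

  ann_a <- annotation(cfg$genotypes[1], do.call(rbind, ga), do.call(rbind, ea))
  ann_b <- annotation(cfg$genotypes[2], do.call(rbind, gb), do.call(rbind, eb))
  blocks <- data.frame(ref_chrom = chrom, ref_start = 0, ref_end = cursor + 10000,
                       qry_chrom = chrom, qry_start = 0, qry_end = cursor + 10000,
                       orientation = "same", stringsAsFactors = FALSE)
  fixture <- list(cfg = cfg,
                  annotations = setNames(list(ann_a, ann_b), cfg$genotypes),
                  hits_ab = do.call(rbind, hab), hits_ba = do.call(rbind, hba),
                  blocks = blocks, truth = do.call(rbind, truth),
                  exon_sources = src_map)
  class(fixture) <- "sg_fixture"
  fixture
}

#' @export
print.sg_fixture <- function(x, ...) {
  cat(sprintf("sg_fixture: %d cases (%s); seed %d\n", nrow(x$truth),
              paste(names(table(x$truth$class)), table(x$truth$class),
                    sep = "=", collapse = ", "), x$cfg$seed))
  invisible(x)
}

#' Generate exon-count matrices for a fixture
#'
#' Every source (true) gene draws one per-tissue log2 expression profile:
#' baseline `mean_log2_tpm` plus iid per-tissue effects of sd `sigma/sqrt(2)`,
#' so two distinct source genes differ per tissue by N(0, sigma^2) while all
#' exons of one source share its profile. Expected exon counts scale with exon
#' length (gene rate x length / mean length); observed counts are negative
#' binomial with the configured dispersion, replicates iid given tissue. Each
#' annotation receives the libraries of its own genotype.
#'
#' @param fixture an `sg_fixture` from [generate_annotation_pair()].
#' @param cfg the fixture's [fixture_config()] (defaults to `fixture$cfg`).
#' @return list with `counts` (named list of [exon_counts()] per genotype,
#'   each carrying an `expected_mu` attribute of expected counts per tissue)
#'   and `libraries` (the combined [library_sheet()]).
#' @export
generate_expression <- function(fixture, cfg = fixture$cfg) {
  set.seed(cfg$seed + 1L)
  sources <- sort(unique(fixture$exon_sources))
  eff <- matrix(rnorm(length(sources) * cfg$n_tissues,
                      sd = cfg$sigma / sqrt(2)),
                nrow = length(sources), dimnames = list(sources, NULL))
  log2_rate <- cfg$mean_log2_tpm + eff
  mean_len <- mean(cfg$exon_len_range)

  tissues <- sprintf("T%02d", seq_len(cfg$n_tissues))
  libs <- do.call(rbind, lapply(cfg$genotypes, function(gt) {
    expand.grid(replicate = seq_len(cfg$n_replicates), tissue = tissues,
                genotype = gt, stringsAsFactors = FALSE)
  }))
  libs$library_id <- sprintf("%s-%s-R%d", libs$genotype, libs$tissue, libs$replicate)
  sheet <- library_sheet(libs$library_id, libs$genotype, libs$tissue, libs$replicate)

  counts <- list()
  for (gt in cfg$genotypes) {
    ann <- fixture$annotations[[gt]]
    ex <- ann$exons
    src <- fixture$exon_sources[ex$exon_id]
    if (anyNA(src)) stop("exon(s) without a source profile: ",
                         paste(head(ex$exon_id[is.na(src)]), collapse = ", "))
    mu_tissue <- 2^log2_rate[src, , drop = FALSE] * (ex$length / mean_len)
    gt_libs <- sheet[sheet$genotype == gt, , drop = FALSE]
    tissue_idx <- match(gt_libs$tissue, tissues)
    mu_full <- mu_tissue[, tissue_idx, drop = FALSE]
    m <- matrix(rnbinom(length(mu_full), mu = as.vector(mu_full),
                        size = 1 / cfg$nb_dispersion),
                nrow = nrow(ex),
                dimnames = list(ex$exon_id, gt_libs$library_id))
    ec <- exon_counts(m, data.frame(exon_id = ex$exon_id, gene_id = ex$gene_id,
                                    length = ex$length, stringsAsFactors = FALSE),
                      sheet)
    attr(ec, "expected_mu") <- mu_tissue
    counts[[gt]] <- ec
  }
  list(counts = counts, libraries = sheet)
}

#' Write a fixture to disk as plain-text pipeline inputs
#'
#' Emits, under `dir`: two GFF3 annotations, 12-column BLAST tables in both
#' directions (keyed by representative transcript IDs, 1-based subject
#' coordinates), a show-coords-style block table, one wide exon-count TSV per
#' annotation, the library sheet, and the truth table. These files are valid
#' inputs to [run_pipeline()].
#'
#' @param fixture an `sg_fixture`.
#' @param expr output of [generate_expression()] for the same fixture.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture_set <- function(fixture, expr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gts <- fixture$cfg$genotypes
  paths <- c(
    gff_a = file.path(dir, paste0(gts[1], ".gff3")),
    gff_b = file.path(dir, paste0(gts[2], ".gff3")),
    hits_ab = file.path(dir, "hits_ab.tsv"),
    hits_ba = file.path(dir, "hits_ba.tsv"),
    coords = file.path(dir, "blocks.coords"),
    counts_a = file.path(dir, paste0("counts_", gts[1], ".tsv")),
    counts_b = file.path(dir, paste0("counts_", gts[2], ".tsv")),
    libraries = file.path(dir, "libraries.tsv"),
    truth = file.path(dir, "truth.tsv"))

  write_gff3(fixture$annotations[[gts[1]]], paths[["gff_a"]])
  write_gff3(fixture$annotations[[gts[2]]], paths[["gff_b"]])

  tx_of <- function(ann) setNames(ann$genes$transcript_id, ann$genes$gene_id)
  write_hits <- function(hits, q_ann, s_ann, path) {
    qt <- tx_of(q_ann); st <- tx_of(s_ann)
    df <- data.frame(
      qseqid = unname(qt[hits$query_gene]), sseqid = unname(st[hits$subject_gene]),
      pident = 98.5, length = hits$match_length, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = hits$match_length,
      sstart = hits$sstart + 1L, send = hits$send,
      evalue = hits$evalue, bitscore = 500,
      stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  a <- fixture$annotations[[gts[1]]]; b <- fixture$annotations[[gts[2]]]
  write_hits(fixture$hits_ab, a, b, paths[["hits_ab"]])
  write_hits(fixture$hits_ba, b, a, paths[["hits_ba"]])

  bl <- fixture$blocks
  coord_lines <- c(
    "NUCMER", "",
    "[S1]\t[E1]\t[S2]\t[E2]\t[LEN 1]\t[LEN 2]\t[% IDY]\t[TAGS]",
    sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%.2f\t%s\t%s",
            bl$ref_start + 1, bl$ref_end,
            ifelse(bl$orientation == "same", bl$qry_start + 1, bl$qry_end),
            ifelse(bl$orientation == "same", bl$qry_end, bl$qry_start + 1),
            bl$ref_end - bl$ref_start, bl$qry_end - bl$qry_start,
            99.0, bl$ref_chrom, bl$qry_chrom))
  writeLines(coord_lines, paths[["coords"]])

  write_counts <- function(ec, path) {
    df <- data.frame(exon_id = ec$exons$exon_id, gene_id = ec$exons$gene_id,
                     length = ec$exons$length, ec$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_counts(expr$counts[[gts[1]]], paths[["counts_a"]])
  write_counts(expr$counts[[gts[2]]], paths[["counts_b"]])

  write.table(expr$libraries, paths[["libraries"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fixture$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
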