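#' Reduce BLAST hits to the single best hit per gene pair
#'
#' Hits at or above `max_evalue` are discarded (strict `< max_evalue` is
#' retained). Among the remaining hits of each (query gene, subject gene) pair,
#' the hit with the smallest e-value is kept; ties are broken by the largest
#' aligned length, then by subject coordinates for determinism. Idempotent.
#'
#' @param hits data.frame of hits as returned by [read_blast_tab()].
#' @param max_evalue strict e-value cutoff (default 1e-4).
#' @return filtered, deduplicated hits data.frame.
#' @export
best_hits <- function(hits, max_evalue = 1e-4) {
  hits <- hits[hits$evalue < max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) { rownames(hits) <- NULL; return(hits) }
  o <- order(hits$query_gene, hits$subject_gene, hits$evalue,
             -hits$match_length, hits$sstart, hits$send)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(hits[, c("query_gene", "subject_gene")])
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Keep hits consistent with a syntenic block
#'
#' A hit survives iff some block (reference side = query annotation, query side
#' = subject annotation) exists whose reference interval, extended by
#' `margin_bp` on both ends, overlaps the query gene's span, and whose query
#' interval, equally extended, overlaps the subject gene's span, with matching
#' chromosomes on both sides. Overlap (not containment) is used so genes
#' straddling block edges are not lost.
#'
#' @param hits hits data.frame (gene-keyed).
#' @param blocks blocks from [read_show_coords()]; the reference genome must be
#'   the query annotation's genome.
#' @param query_ann,subject_ann [annotation] objects supplying gene spans.
#' @param margin_bp extension on each block end (default 500 kb).
#' @return subset of `hits`.
#' @export
filter_by_synteny <- function(hits, blocks, query_ann, subject_ann,
                              margin_bp = 500000) {
  if (nrow(hits) == 0L) return(hits)
  qg <- query_ann$genes
  sg <- subject_ann$genes
  missing_q <- setdiff(unique(hits$query_gene), qg$gene_id)
  missing_s <- setdiff(unique(hits$subject_gene), sg$gene_id)
  if (length(missing_q) || length(missing_s)) {
    stop("hits reference genes absent from the annotations: ",
         paste(head(c(missing_q, missing_s), 10L), collapse = ", "))
  }
  q_chrom <- qg[hits$query_gene, "chrom"]
  q_start <- qg[hits$query_gene, "start"]
  q_end <- qg[hits$query_gene, "end"]
  s_chrom <- sg[hits$subject_gene, "chrom"]
  s_start <- sg[hits$subject_gene, "start"]
  s_end <- sg[hits$subject_gene, "end"]

  keep <- rep(FALSE, nrow(hits))
  for (b in seq_len(nrow(blocks))) {
    rs <- max(0, blocks$ref_start[b] - margin_bp); re <- blocks$ref_end[b] + margin_bp
    qs <- max(0, blocks$qry_start[b] - margin_bp); qe <- blocks$qry_end[b] + margin_bp
    hit_b <- !keep &
      q_chrom == blocks$ref_chrom[b] & s_chrom == blocks$qry_chrom[b] &
      q_start < re & q_end > rs &
      s_start < qe & s_end > qs
    keep[hit_b] <- TRUE
    if (all(keep)) break
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify per-query-gene correspondences
#'
#' Every gene of the query annotation is classified by how many subject genes
#' its surviving hits reach: `none` (0), `single` (1), or `multiple` (>= 2).
#' A correspondence is `proximal` when all subject genes lie on one chromosome
#' and their per-chromosome rank spread is at most `window`.
#'
#' @param hits best-deduplicated, synteny-filtered hits.
#' @param query_ann,subject_ann [annotation] objects.
#' @param window maximum rank spread (default 5 gene models).
#' @return data.frame with columns `query_gene`, `classification`,
#'   `subject_genes` (comma-separated, ordered by subject start), `n_subjects`,
#'   `proximal`.
#' @export
classify_correspondences <- function(hits, query_ann, subject_ann, window = 5) {
  sg <- subject_ann$genes
  subj_sets <- split(hits$subject_gene, hits$query_gene)
  q_with <- names(subj_sets)
  info <- lapply(subj_sets, function(subs) {
    subs <- unique(subs)
    subs <- subs[order(sg[subs, "chrom"], sg[subs, "start"], subs)]
    chroms <- sg[subs, "chrom"]
    ranks <- sg[subs, "rank"]
    list(set = paste(subs, collapse = ","), n = length(subs),
         prox = length(unique(chroms)) == 1L && (max(ranks) - min(ranks)) <= window)
  })
  all_q <- query_ann$genes$gene_id
  idx <- match(all_q, q_with)
  n_sub <- ifelse(is.na(idx), 0L, vapply(info, `[[`, integer(1), "n")[idx])
  data.frame(
    query_gene = all_q,
    classification = ifelse(n_sub == 0L, "none",
                            ifelse(n_sub == 1L, "single", "multiple")),
    subject_genes = ifelse(is.na(idx), "",
                           vapply(info, `[[`, character(1), "set")[idx]),
    n_subjects = as.integer(n_sub),
    proximal = ifelse(is.na(idx), NA, vapply(info, `[[`, logical(1), "prox")[idx]),
    stringsAsFactors = FALSE, row.names = NULL)
}

split_gene_field <- function(x) strsplit(x, ",", fixed = TRUE)

#' Resolve reciprocal correspondences
#'
#' Confirms relationships across the two BLAST directions. A one-to-one pair
#' (g, h) requires g -> {h} and h -> {g}, both `single`. A one-to-many record
#' (g, {h1..hk}) requires g -> multiple subjects and every hi -> {g} `single`
#' (exclusivity); records failing exclusivity are dropped with a message.
#'
#' @param a_to_b,b_to_a correspondence tables from [classify_correspondences()]
#'   computed in the two directions with identical parameters.
#' @return list with `one_to_one` (data.frame `gene_a`, `gene_b`) and
#'   `one_to_many` (data.frame `single_gene`, `many_genes` comma-separated,
#'   `n_many`). The `one_to_many` single gene lives in the A annotation; the
#'   many genes live in B.
#' @export
reciprocal_resolve <- function(a_to_b, b_to_a) {
  back <- setNames(b_to_a$subject_genes, b_to_a$query_gene)
  back_class <- setNames(b_to_a$classification, b_to_a$query_gene)

  one_to_one <- data.frame(gene_a = character(0), gene_b = character(0),
                           stringsAsFactors = FALSE)
  one_to_many <- data.frame(single_gene = character(0), many_genes = character(0),
                            n_many = integer(0), stringsAsFactors = FALSE)
  singles <- a_to_b[a_to_b$classification == "single", , drop = FALSE]
  if (nrow(singles)) {
    h <- singles$subject_genes
    ok <- !is.na(back_class[h]) & back_class[h] == "single" &
      back[h] == singles$query_gene
    ok[is.na(ok)] <- FALSE
    one_to_one <- data.frame(gene_a = singles$query_gene[ok],
                             gene_b = h[ok], stringsAsFactors = FALSE)
  }
  multis <- a_to_b[a_to_b$classification == "multiple", , drop = FALSE]
  if (nrow(multis)) {
    keep <- logical(nrow(multis))
    for (i in seq_len(nrow(multis))) {
      hs <- split_gene_field(multis$subject_genes[i])[[1]]
      cls <- back_class[hs]
      ok <- !anyNA(cls) && all(cls == "single") &&
        all(back[hs] == multis$query_gene[i])
      if (!ok) {
        message("dropping non-exclusive one-to-many relation for ",
                multis$query_gene[i])
      }
      keep[i] <- ok
    }
    m <- multis[keep, , drop = FALSE]
    one_to_many <- data.frame(single_gene = m$query_gene,
                              many_genes = m$subject_genes,
                              n_many = m$n_subjects,
                              stringsAsFactors = FALSE)
  }
  rownames(one_to_one) <- rownames(one_to_many) <- NULL
  list(one_to_one = one_to_one, one_to_many = one_to_many)
}

#' Tandem-duplication overlap ratio (L1/L2)
#'
#' On the subject transcript, L2 is the total length of the union of all
#' aligned intervals and L1 is the total length of positions covered by the
#' alignments of two or more distinct query genes. Tandem duplicates align to
#' the same region of the subject (high L1/L2); genuinely split genes align to
#' disjoint regions (L1/L2 near 0). Candidates are excluded when the ratio is
#' >= 0.1 (the pass criterion is strict `< 0.1`).
#'
#' @param query_hits hits of >= 2 distinct query genes onto one subject gene,
#'   with `sstart`/`send` subject intervals (0-based half-open).
#' @return L1/L2 in \[0, 1\].
#' @export
tandem_ratio <- function(query_hits) {
  if (nrow(query_hits) == 0L) stop("no aligned bases on subject (L2 = 0)")
  if (length(unique(query_hits$subject_gene)) > 1L) {
    stop("query_hits must target a single subject gene")
  }
  ir_all <- IRanges::IRanges(start = query_hits$sstart + 1L, end = query_hits$send)
  l2 <- sum(IRanges::width(IRanges::reduce(ir_all)))
  if (l2 == 0L) stop("no aligned bases on subject (L2 = 0)")
  # merge intervals within each query gene first so one gene's overlapping
  # HSPs do not count as multi-coverage
  per_gene <- lapply(split(seq_len(nrow(query_hits)), query_hits$query_gene),
                     function(idx) IRanges::reduce(ir_all[idx]))
  cov <- IRanges::coverage(do.call(c, unname(per_gene)))
  l1 <- sum(S4Vectors::runLength(cov)[S4Vectors::runValue(cov) >= 2L])
  l1 / l2
}

#' Build split-gene candidates from one-to-many relations
#'
#' Each one-to-many relation (one merged gene in annotation A, >= 2 split genes
#' in annotation B) is evaluated against the candidacy filters: split genes
#' pairwise non-overlapping, on one strand, not a tandem duplication
#' (L1/L2 < `tandem_max`), all involved genes expressed, and split genes
#' proximal (rank spread <= `window`). Failing candidates are retained with
#' per-filter pass/fail flags so exclusion statistics remain computable; only
#' candidates passing every filter are `testable`.
#'
#' @param one_to_many data.frame from [reciprocal_resolve()].
#' @param merged_ann annotation holding the single (merged) genes.
#' @param split_ann annotation holding the split genes.
#' @param hits post-filter hits in the split-annotation -> merged-annotation
#'   direction (split genes as queries), used for the tandem ratio.
#' @param expressed character vector of expressed gene IDs (union over both
#'   annotations; see [expressed_genes()]).
#' @param window rank-proximity window (default 5).
#' @param tandem_max strict upper bound on L1/L2 (default 0.1).
#' @return data.frame of candidates with columns `merged_annotation`,
#'   `merged_gene`, `split_annotation`, `split_genes` (comma-separated, sorted
#'   by genomic start), `n_split`, `tandem_ratio`, the filter flags
#'   `overlap_pass`, `strand_pass`, `tandem_pass`, `expressed_pass`,
#'   `proximal_pass`, plus `testable` and `corroboration` ("unset").
#' @export
build_split_candidates <- function(one_to_many, merged_ann, split_ann, hits,
                                   expressed, window = 5, tandem_max = 0.1) {
  n <- nrow(one_to_many)
  sg <- split_ann$genes
  out <- vector("list", n)
  for (i in seq_len(n)) {
    merged <- one_to_many$single_gene[i]
    splits <- split_gene_field(one_to_many$many_genes[i])[[1]]
    missing <- setdiff(splits, sg$gene_id)
    if (length(missing)) {
      stop("split gene(s) absent from the split annotation: ",
           paste(missing, collapse = ", "))
    }
    splits <- splits[order(sg[splits, "chrom"], sg[splits, "start"], splits)]
    st <- sg[splits, "start"]; en <- sg[splits, "end"]
    chroms <- sg[splits, "chrom"]; strands <- sg[splits, "strand"]
    ranks <- sg[splits, "rank"]

    k <- length(splits)
    overlap <- FALSE
    for (a in seq_len(k - 1L)) {
      same <- chroms[-seq_len(a)] == chroms[a]
      if (any(same & st[-seq_len(a)] < en[a] & en[-seq_len(a)] > st[a])) {
        overlap <- TRUE
        break
      }
    }
    strand_ok <- length(unique(strands)) == 1L
    prox_ok <- length(unique(chroms)) == 1L && (max(ranks) - min(ranks)) <= window

    h <- hits[hits$subject_gene == merged & hits$query_gene %in% splits, , drop = FALSE]
    tr <- if (nrow(h)) tandem_ratio(h) else NA_real_
    tandem_ok <- !is.na(tr) && tr < tandem_max

    expr_ok <- all(c(merged, splits) %in% expressed)

    out[[i]] <- data.frame(
      merged_annotation = merged_ann$genotype,
      merged_gene = merged,
      split_annotation = split_ann$genotype,
      split_genes = paste(splits, collapse = ","),
      n_split = k,
      tandem_ratio = tr,
      overlap_pass = !overlap,
      strand_pass = strand_ok,
      tandem_pass = tandem_ok,
      expressed_pass = expr_ok,
      proximal_pass = prox_ok,
      stringsAsFactors = FALSE
    )
  }
  cand <- if (n) do.call(rbind, out) else data.frame(
    merged_annotation = character(0), merged_gene = character(0),
    split_annotation = character(0), split_genes = character(0),
    n_split = integer(0), tandem_ratio = numeric(0),
    overlap_pass = logical(0), strand_pass = logical(0),
    tandem_pass = logical(0), expressed_pass = logical(0),
    proximal_pass = logical(0), stringsAsFactors = FALSE)
  cand$testable <- cand$overlap_pass & cand$strand_pass & cand$tandem_pass &
    cand$expressed_pass & cand$proximal_pass
  cand$candidate_id <- if (nrow(cand)) {
    paste0(cand$merged_annotation, ":", cand$merged_gene, "|",
           cand$split_annotation, ":", cand$split_genes)
  } else character(0)
  cand$corroboration <- rep("unset", nrow(cand))
  rownames(cand) <- NULL
  cand
}

#' Corroborate candidates across two pairwise comparisons
#'
#' Both candidate tables must share one annotation (A). A merged-side A gene is
#' `corroborated` when it appears as the merged gene in both comparisons (it
#' corresponds to multiple genes in both alternates); a split-side A gene set
#' is `corroborated` when the identical gene-ID set corresponds to a single
#' gene in both alternates. Everything else is `unique`.
#'
#' @param candidates_ab,candidates_ac candidate tables from
#'   [build_split_candidates()] for the A-B and A-C comparisons.
#' @param label_a the shared annotation's genotype label; inferred when the
#'   tables share exactly one label.
#' @return list with both tables, `corroboration` filled in.
#' @export
corroborate <- function(candidates_ab, candidates_ac, label_a = NULL) {
  labels <- function(x) unique(c(x$merged_annotation, x$split_annotation))
  if (is.null(label_a)) {
    shared <- intersect(labels(candidates_ab), labels(candidates_ac))
    if (length(shared) != 1L) {
      stop("cannot infer the shared annotation; pass label_a explicitly")
    }
    label_a <- shared
  }
  key_sets <- function(x) {
    merged_a <- x$merged_gene[x$merged_annotation == label_a]
    split_a <- x$split_genes[x$split_annotation == label_a]
    list(merged = unique(merged_a), split = unique(split_a))
  }
  mark <- function(x, other) {
    cor <- rep("unique", nrow(x))
    is_merged_a <- x$merged_annotation == label_a
    cor[is_merged_a & x$merged_gene %in% other$merged] <- "corroborated"
    is_split_a <- x$split_annotation == label_a
    cor[is_split_a & x$split_genes %in% other$split] <- "corroborated"
    x$corroboration <- cor
    x
  }
  list(candidates_ab = mark(candidates_ab, key_sets(candidates_ac)),
       candidates_ac = mark(candidates_ac, key_sets(candidates_ab)))
}
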