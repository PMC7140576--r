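#' Construct an annotation object
#'
#' An annotation holds one gene model per gene: the gene span, strand, and the
#' ordered exon intervals of the representative transcript (the transcript with
#' the longest total CDS). All coordinates are 0-based half-open. A dense
#' per-chromosome rank (0, 1, 2, ...) ordered by start coordinate is attached;
#' rank differences are the package's canonical gene-proximity measure.
#'
#' @param genotype single string labelling the genotype/assembly.
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand` ("+"/"-"),
#'   `start`, `end` (0-based half-open span), `cds_length`, and optionally
#'   `transcript_id` (representative transcript).
#' @param exons data.frame with columns `gene_id`, `start`, `end` (0-based
#'   half-open exon intervals of the representative transcript).
#' @return object of class `annotation` with components `genotype`, `genes`
#'   (with a `rank` and `n_exons` column added), and `exons` (with `exon_id`
#'   and `length` columns added).
#' @export
annotation <- function(genotype, genes, exons) {
  stopifnot(is.character(genotype), length(genotype) == 1L)
  req_g <- c("gene_id", "chrom", "strand", "start", "end", "cds_length")
  if (!all(req_g %in% names(genes))) {
    stop("genes is missing columns: ", paste(setdiff(req_g, names(genes)), collapse = ", "))
  }
  req_e <- c("gene_id", "start", "end")
  if (!all(req_e %in% names(exons))) {
    stop("exons is missing columns: ", paste(setdiff(req_e, names(exons)), collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id: ", paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start >= genes$end)) stop("gene span must satisfy start < end")
  if (any(exons$start >= exons$end)) stop("every exon must have length >= 1")
  if (!all(exons$gene_id %in% genes$gene_id)) {
    stop("exons reference unknown genes: ",
         paste(unique(setdiff(exons$gene_id, genes$gene_id)), collapse = ", "))
  }
  if (!all(genes$gene_id %in% exons$gene_id)) {
    stop("genes with no exons: ",
         paste(setdiff(genes$gene_id, exons$gene_id), collapse = ", "))
  }

  # order exons by gene then start; enforce non-overlap and containment
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), , drop = FALSE]
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  span_start <- setNames(genes$start, genes$gene_id)
  span_end <- setNames(genes$end, genes$gene_id)
  for (g in names(by_gene)) {
    idx <- by_gene[[g]]
    s <- exons$start[idx]; e <- exons$end[idx]
    if (length(idx) > 1L && any(s[-1L] < e[-length(e)])) {
      stop("overlapping exons in gene ", g)
    }
    if (s[1L] < span_start[[g]] || e[length(e)] > span_end[[g]]) {
      stop("exon outside gene span in gene ", g)
    }
  }
  n_ex <- vapply(by_gene, length, integer(1))
  genes$n_exons <- as.integer(n_ex[genes$gene_id])

  # dense per-chromosome rank by start (gene_id breaks coordinate ties)
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  genes$rank <- as.integer(stats::ave(genes$start, genes$chrom,
                                      FUN = function(x) seq_along(x) - 1L))
  rownames(genes) <- genes$gene_id

  exon_index <- stats::ave(seq_len(nrow(exons)), exons$gene_id, FUN = seq_along)
  exons$exon_id <- paste0(exons$gene_id, ":", exon_index)
  exons$length <- exons$end - exons$start
  rownames(exons) <- NULL

  structure(list(genotype = genotype, genes = genes, exons = exons),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("annotation '%s': %d genes, %d exons, %d chromosome(s)\n",
              x$genotype, nrow(x$genes), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Representative transcript to gene map
#'
#' @param ann an [annotation].
#' @return named character vector mapping representative transcript IDs to
#'   gene IDs. Empty if the annotation carries no `transcript_id` column.
#' @export
transcript_map <- function(ann) {
  g <- ann$genes
  if (is.null(g$transcript_id)) return(setNames(character(0), character(0)))
  setNames(g$gene_id, g$transcript_id)
}

#' Read a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS features, picks the representative transcript of
#' each gene as the one with the longest total CDS (ties broken by
#' lexicographically smallest transcript ID), and converts GFF3 1-based
#' inclusive coordinates to internal 0-based half-open intervals. Genes with no
#' CDS on any transcript are skipped with a warning; an exon whose Parent is
#' not a known mRNA is a hard error.
#'
#' @param path GFF3 file path.
#' @param genotype genotype label; defaults to the file name without extension.
#' @return an [annotation].
#' @export
read_gff3 <- function(path, genotype = NULL) {
  if (is.null(genotype)) genotype <- sub("\\.gff3?$", "", basename(path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent   # CharacterList

  first_parent <- function(i) {
    p <- parents[[i]]
    if (length(p) == 0L) NA_character_ else p
  }

  is_gene <- type == "gene"
  is_mrna <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  is_cds  <- type == "CDS"

  gene_ids <- ids[is_gene]
  if (anyNA(gene_ids)) stop("gene feature without ID attribute in ", path)
  gene_tbl <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE
  )

  mrna_idx <- which(is_mrna)
  tx_id <- ids[mrna_idx]
  tx_parent <- vapply(mrna_idx, first_parent, character(1))
  if (anyNA(tx_parent)) {
    stop("mRNA feature without Parent attribute: ",
         paste(tx_id[is.na(tx_parent)], collapse = ", "))
  }
  tx2gene <- setNames(tx_parent, tx_id)
  unknown_gene <- setdiff(unique(tx_parent), gene_tbl$gene_id)
  if (length(unknown_gene)) {
    stop("mRNA Parent(s) not found among gene features: ",
         paste(unknown_gene, collapse = ", "))
  }

  # total CDS length per transcript
  cds_idx <- which(is_cds)
  cds_len <- setNames(numeric(0), character(0))
  if (length(cds_idx)) {
    cds_parents <- parents[cds_idx]
    w <- GenomicRanges::width(gr)[cds_idx]
    flat_p <- unlist(cds_parents, use.names = FALSE)
    flat_w <- rep(w, lengths(cds_parents))
    bad <- setdiff(unique(flat_p), names(tx2gene))
    if (length(bad)) stop("CDS Parent(s) are not known mRNAs: ", paste(bad, collapse = ", "))
    cds_len <- tapply(flat_w, flat_p, sum)
  }

  # representative transcript per gene: max CDS, tie -> lexicographically first
  tx_with_cds <- names(cds_len)
  if (length(tx_with_cds) == 0L) stop("no CDS features found in ", path)
  tx_tbl <- data.frame(transcript_id = tx_with_cds,
                       gene_id = unname(tx2gene[tx_with_cds]),
                       cds = as.numeric(cds_len),
                       stringsAsFactors = FALSE)
  tx_tbl <- tx_tbl[order(tx_tbl$gene_id, -tx_tbl$cds, tx_tbl$transcript_id), ]
  rep_tbl <- tx_tbl[!duplicated(tx_tbl$gene_id), ]

  no_cds <- setdiff(gene_tbl$gene_id, rep_tbl$gene_id)
  if (length(no_cds)) {
    warning("skipping ", length(no_cds), " gene(s) with no CDS on any transcript: ",
            paste(head(no_cds, 10L), collapse = ", "),
            if (length(no_cds) > 10L) ", ..." else "")
    gene_tbl <- gene_tbl[!gene_tbl$gene_id %in% no_cds, , drop = FALSE]
  }

  # exons of the representative transcripts
  exon_idx <- which(is_exon)
  if (length(exon_idx) == 0L) stop("no exon features found in ", path)
  exon_parents <- parents[exon_idx]
  flat_ep <- unlist(exon_parents, use.names = FALSE)
  orphan <- setdiff(unique(flat_ep), names(tx2gene))
  if (length(orphan)) {
    stop("exon feature(s) whose Parent is not a known mRNA: ",
         paste(orphan, collapse = ", "))
  }
  no_parent <- lengths(exon_parents) == 0L
  if (any(no_parent)) {
    lab <- ids[exon_idx][no_parent]
    lab[is.na(lab)] <- "<unnamed exon>"
    stop("exon feature(s) without Parent: ", paste(unique(lab), collapse = ", "))
  }
  rep_set <- setNames(rep_tbl$gene_id, rep_tbl$transcript_id)
  flat_row <- rep(exon_idx, lengths(exon_parents))
  keep <- flat_ep %in% names(rep_set)
  exon_tbl <- data.frame(
    gene_id = unname(rep_set[flat_ep[keep]]),
    start = GenomicRanges::start(gr)[flat_row[keep]] - 1L,
    end = GenomicRanges::end(gr)[flat_row[keep]],
    stringsAsFactors = FALSE
  )

  gene_tbl$cds_length <- as.numeric(setNames(rep_tbl$cds, rep_tbl$gene_id)[gene_tbl$gene_id])
  gene_tbl$transcript_id <- setNames(rep_tbl$transcript_id, rep_tbl$gene_id)[gene_tbl$gene_id]

  annotation(genotype, gene_tbl, exon_tbl)
}

#' Write an annotation to GFF3
#'
#' Emits one gene, one mRNA (the representative transcript), its exons, and a
#' CDS per exon. Re-reading the file reproduces the gene spans, strands, and
#' exon intervals exactly.
#'
#' @param ann an [annotation].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes
  e <- ann$exons
  tx_id <- if (!is.null(g$transcript_id)) g$transcript_id else paste0(g$gene_id, "_T001")
  names(tx_id) <- g$gene_id
  ge_strand <- setNames(g$strand, g$gene_id)
  ge_chrom <- setNames(g$chrom, g$gene_id)

  feat <- function(chrom, start0, end0, strand, type, id, parent,
                   phase = NA_integer_) {
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      strand = strand,
      type = type,
      ID = id,
      Parent = IRanges::CharacterList(as.list(parent)),
      phase = phase
    )
  }
  gene_gr <- feat(g$chrom, g$start, g$end, g$strand, "gene", g$gene_id,
                  replicate(nrow(g), character(0), simplify = FALSE))
  mrna_gr <- feat(g$chrom, g$start, g$end, g$strand, "mRNA", unname(tx_id),
                  as.list(g$gene_id))
  ex_par <- unname(tx_id[e$gene_id])
  exon_gr <- feat(ge_chrom[e$gene_id], e$start, e$end, ge_strand[e$gene_id],
                  "exon", paste0(ex_par, ".exon", seq_len(nrow(e))), as.list(ex_par))
  cds_gr <- feat(ge_chrom[e$gene_id], e$start, e$end, ge_strand[e$gene_id],
                 "CDS", paste0(ex_par, ".cds", seq_len(nrow(e))), as.list(ex_par),
                 phase = 0L)
  all_gr <- c(gene_gr, mrna_gr, exon_gr, cds_gr)
  rtracklayer::export(all_gr, path, format = "gff3")
  invisible(path)
}

#' Read nucmer show-coords output into syntenic blocks
#'
#' Accepts the tab-delimited (`show-coords -T`) or column-aligned default
#' layouts: header, separator, and bracketed column-label lines are skipped;
#' `|` column separators are tolerated. Each data row yields one block with
#' 0-based half-open reference and query intervals. Rows whose query interval
#' is given end-before-start are normalized and flagged `inverted`.
#'
#' @param path show-coords output file.
#' @return data.frame with columns `ref_chrom`, `ref_start`, `ref_end`,
#'   `qry_chrom`, `qry_start`, `qry_end`, `orientation` ("same"/"inverted").
#' @export
read_show_coords <- function(path) {
  lines <- readLines(path)
  out <- vector("list", length(lines))
  n_out <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (grepl("\\[", ln) || grepl("^=+$", trimws(ln))) next
    toks <- strsplit(trimws(ln), "[ \t|]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) < 6L) next   # NUCMER banner / file-path header lines
    coord <- suppressWarnings(as.numeric(toks[1:4]))
    if (anyNA(coord)) {
      stop("non-numeric coordinate field on line ", i, " of ", path, ": ", ln)
    }
    ref_chrom <- toks[length(toks) - 1L]
    qry_chrom <- toks[length(toks)]
    s1 <- coord[1]; e1 <- coord[2]; s2 <- coord[3]; e2 <- coord[4]
    inv <- s2 > e2
    if (s1 > e1) { tmp <- s1; s1 <- e1; e1 <- tmp }   # defensive; ref normally forward
    if (inv) { tmp <- s2; s2 <- e2; e2 <- tmp }
    n_out <- n_out + 1L
    out[[n_out]] <- data.frame(
      ref_chrom = ref_chrom, ref_start = s1 - 1, ref_end = e1,
      qry_chrom = qry_chrom, qry_start = s2 - 1, qry_end = e2,
      orientation = if (inv) "inverted" else "same",
      stringsAsFactors = FALSE
    )
  }
  if (n_out == 0L) {
    return(data.frame(ref_chrom = character(0), ref_start = numeric(0),
                      ref_end = numeric(0), qry_chrom = character(0),
                      qry_start = numeric(0), qry_end = numeric(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(n_out)])
}

#' Read tabular BLAST hits and re-key transcripts to genes
#'
#' Reads 12-column outfmt-6-style hits (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Query and subject
#' transcript IDs are mapped to gene IDs; subject coordinates are normalized to
#' a 0-based half-open interval with start < end.
#'
#' @param path tabular BLAST file (no header).
#' @param transcript_to_gene named character vector, transcript ID -> gene ID.
#'   Must cover every transcript ID present in the file.
#' @return data.frame with columns `query_gene`, `subject_gene`, `evalue`,
#'   `match_length`, `sstart`, `send` (subject interval, 0-based half-open).
#' @export
read_blast_tab <- function(path, transcript_to_gene) {
  empty <- data.frame(query_gene = character(0), subject_gene = character(0),
                      evalue = numeric(0), match_length = integer(0),
                      sstart = numeric(0), send = numeric(0),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("qseqid", "sseqid", "pident", "length",
                                  "mismatch", "gapopen", "qstart", "qend",
                                  "sstart", "send", "evalue", "bitscore"))
  if (nrow(tab) == 0L) return(empty)
  missing <- setdiff(unique(c(tab$qseqid, tab$sseqid)), names(transcript_to_gene))
  if (length(missing)) {
    stop("transcript ID(s) absent from transcript_to_gene map: ",
         paste(head(missing, 20L), collapse = ", "),
         if (length(missing) > 20L) ", ..." else "")
  }
  lo <- pmin(tab$sstart, tab$send)
  hi <- pmax(tab$sstart, tab$send)
  data.frame(
    query_gene = unname(transcript_to_gene[tab$qseqid]),
    subject_gene = unname(transcript_to_gene[tab$sseqid]),
    evalue = tab$evalue,
    match_length = as.integer(tab$length),
    sstart = lo - 1,
    send = hi,
    stringsAsFactors = FALSE
  )
}
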