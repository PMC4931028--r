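#' Load a reference genome from FASTA
#'
#' Sequences are upper-cased and IUPAC ambiguity codes other than `N` are
#' replaced by `N` (with a warning). Record names must be unique.
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return a named [Biostrings::DNAStringSet] with one entry per chromosome.
#' @export
load_genome <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate record name(s) in ", path, ": ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(seqs) <- nm
  chars <- toupper(as.character(seqs))
  n_amb <- sum(vapply(chars, function(s)
    nchar(gsub("[ACGTN]", "", s)), integer(1)))
  if (n_amb > 0L) {
    warning(n_amb, " ambiguity bases mapped to N")
    chars <- vapply(chars, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  Biostrings::DNAStringSet(setNames(chars, nm))
}

#' Extract a (strand-oriented) sequence from a genome
#'
#' @param genome a `DNAStringSet` as returned by [load_genome()].
#' @param interval a [genomic_interval()]; `-` strand returns the reverse
#'   complement of the forward sequence.
#' @return a character scalar.
#' @export
extract_sequence <- function(genome, interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  if (!interval$chrom %in% names(genome))
    stop("unknown chromosome: ", interval$chrom)
  len <- Biostrings::width(genome[interval$chrom])
  if (interval$start < 0L || interval$end > len)
    stop("interval [", interval$start, ",", interval$end,
         ") outside chromosome ", interval$chrom, " of length ", len)
  s <- as.character(Biostrings::subseq(genome[[interval$chrom]],
                                       start = interval$start + 1L,
                                       end = interval$end))
  if (identical(interval$strand, "-")) revcomp(s) else s
}

# lower-level variant used in hot paths (no interval object, no strand)
seq_slice <- function(genome, chrom, start, end) {
  as.character(Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end))
}

#' Load a gene annotation from GFF3 or GTF
#'
#' Builds the gene -> transcript -> exon hierarchy from `Parent=` attributes
#' (GFF3) or `gene_id`/`transcript_id` attributes (GTF), converts coordinates
#' to the internal 0-based half-open convention, records all annotated start
#' and stop codons per transcript (several may exist), and computes the
#' maximum intron length over all transcripts, which the spliced aligner uses
#' as its maximum intron bound.
#'
#' @param path path to a GFF3 or GTF file (extension decides the dialect;
#'   `.gtf` is GTF, everything else GFF3).
#' @return an `annotation_index` object: a list with elements
#'   `genes`, `transcripts`, `exons`, `start_codons`, `stop_codons`
#'   (data frames), `max_intron` and pre-built `GRanges` indices
#'   `exon_gr`/`gene_gr`.
#' @export
load_annotation <- function(path) {
  stopifnot(file.exists(path))
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  # 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end

  get_tx_id <- function(rows) {
    if (fmt == "gtf") return(rows$transcript_id)
    p <- rows$Parent
    vapply(p, function(x) if (length(x)) as.character(x)[1] else NA_character_,
           character(1))
  }
  ex <- df[tolower(df$type) == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("annotation contains no exon features")
  ex_tx <- get_tx_id(ex)
  if (anyNA(ex_tx)) stop("exon without parent transcript in ", path)

  tx_types <- c("mrna", "transcript", "mirna", "ncrna", "lnc_rna", "rna")
  txr <- df[tolower(df$type) %in% tx_types, , drop = FALSE]
  if (fmt == "gtf") {
    tx_ids <- unique(ex_tx)
    tx_gene <- vapply(tx_ids, function(t)
      unique(ex$gene_id[ex_tx == t])[1], character(1))
  } else {
    if (nrow(txr) == 0L) stop("no transcript features in GFF3 ", path)
    tx_ids <- if (!is.null(txr$ID)) as.character(txr$ID) else
      stop("GFF3 transcripts lack ID attributes")
    tx_gene <- vapply(txr$Parent, function(x)
      if (length(x)) as.character(x)[1] else NA_character_, character(1))
    names(tx_gene) <- tx_ids
    tx_gene <- tx_gene[tx_ids]
  }
  if (anyNA(tx_gene)) stop("transcript without parent gene in ", path)

  exons <- data.frame(tx_id = ex_tx, chrom = ex$seqnames,
                      start = ex$start0, end = ex$end0,
                      strand = ex$strand, stringsAsFactors = FALSE)
  exons <- exons[order(exons$tx_id, exons$start), , drop = FALSE]
  exons <- exons[exons$tx_id %in% tx_ids, , drop = FALSE]

  tx_span <- do.call(rbind, lapply(split(exons, exons$tx_id), function(e) {
    data.frame(tx_id = e$tx_id[1], gene_id = NA_character_, chrom = e$chrom[1],
               start = min(e$start), end = max(e$end), strand = e$strand[1],
               stringsAsFactors = FALSE)
  }))
  tx_span$gene_id <- unname(tx_gene[tx_span$tx_id])
  rownames(tx_span) <- NULL

  genes <- do.call(rbind, lapply(split(tx_span, tx_span$gene_id), function(t) {
    data.frame(gene_id = t$gene_id[1], chrom = t$chrom[1],
               start = min(t$start), end = max(t$end), strand = t$strand[1],
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  codon_rows <- function(type_names, from_cds = NULL) {
    cr <- df[tolower(df$type) %in% type_names, , drop = FALSE]
    if (nrow(cr) == 0L) return(NULL)
    data.frame(tx_id = get_tx_id(cr), start = cr$start0, end = cr$end0,
               strand = cr$strand, stringsAsFactors = FALSE)
  }
  starts <- codon_rows(c("start_codon", "start"))
  stops <- codon_rows(c("stop_codon", "stop"))
  # fall back to CDS-derived codons when codon features are absent
  cds <- df[tolower(df$type) == "cds", , drop = FALSE]
  if ((is.null(starts) || is.null(stops)) && nrow(cds) > 0L) {
    cds_tx <- get_tx_id(cds)
    per_tx <- split(seq_len(nrow(cds)), cds_tx)
    mk <- function(which_end) do.call(rbind, lapply(names(per_tx), function(t) {
      rows <- cds[per_tx[[t]], , drop = FALSE]
      plus <- rows$strand[1] == "+"
      first5 <- xor(!plus, which_end == "start")
      if (first5) { s <- min(rows$start0); data.frame(tx_id = t, start = s, end = s + 3L,
                                                      strand = rows$strand[1]) }
      else { e <- max(rows$end0); data.frame(tx_id = t, start = e - 3L, end = e,
                                             strand = rows$strand[1]) }
    }))
    if (is.null(starts)) starts <- mk("start")
    if (is.null(stops)) stops <- mk("stop")
  }
  empty_codon <- data.frame(tx_id = character(0), start = integer(0),
                            end = integer(0), strand = character(0))
  starts <- starts %||% empty_codon
  stops <- stops %||% empty_codon
  starts <- starts[starts$tx_id %in% tx_ids, , drop = FALSE]
  stops <- stops[stops$tx_id %in% tx_ids, , drop = FALSE]

  new_annotation_index(genes, tx_span, exons, starts, stops)
}

# assemble an annotation_index from its component tables (0-based half-open)
new_annotation_index <- function(genes, transcripts, exons, starts, stops) {
  max_intron <- 0L
  for (e in split(exons, exons$tx_id)) {
    ic <- introns_from_exons(as.matrix(e[, c("start", "end")]))
    if (nrow(ic)) max_intron <- max(max_intron, max(ic[, 2L] - ic[, 1L]))
  }
  ann <- structure(list(genes = genes, transcripts = transcripts,
                        exons = exons,
                        start_codons = starts, stop_codons = stops,
                        max_intron = as.integer(max_intron)),
                   class = "annotation_index")
  ann$exon_gr <- annotation_exon_granges(ann)
  ann$gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand, gene_id = genes$gene_id)
  ann
}

annotation_exon_granges <- function(ann) {
  ex <- ann$exons
  gene <- setNames(ann$transcripts$gene_id, ann$transcripts$tx_id)
  GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
                         strand = ex$strand, tx_id = ex$tx_id,
                         gene_id = unname(gene[ex$tx_id]))
}

#' Exon matrix (0-based half-open, sorted) of one annotated transcript
#' @param ann an `annotation_index`.
#' @param tx_id transcript id.
#' @return integer matrix with columns `start`, `end`.
#' @export
transcript_exons <- function(ann, tx_id) {
  e <- ann$exons[ann$exons$tx_id == tx_id, , drop = FALSE]
  if (nrow(e) == 0L) stop("unknown transcript: ", tx_id)
  m <- as.matrix(e[order(e$start), c("start", "end")])
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Intron chain of one annotated transcript
#' @inheritParams transcript_exons
#' @return integer matrix with columns `start`, `end` (possibly 0 rows).
#' @export
transcript_introns <- function(ann, tx_id) introns_from_exons(transcript_exons(ann, tx_id))

#' Write an annotation index back to GFF3
#'
#' Coordinates are converted back to 1-based inclusive. Together with
#' [load_annotation()] this round-trips exactly.
#'
#' @param ann an `annotation_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  lines <- "##gff-version 3"
  fmt_row <- function(chrom, type, s0, e0, strand, attrs)
    paste(chrom, "isopipe", type, s0 + 1L, e0, ".", strand, ".", attrs,
          sep = "\t")
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    lines <- c(lines, fmt_row(g$chrom, "gene", g$start, g$end, g$strand,
                              paste0("ID=", g$gene_id)))
    txs <- ann$transcripts[ann$transcripts$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      t <- txs[j, ]
      lines <- c(lines, fmt_row(t$chrom, "mRNA", t$start, t$end, t$strand,
                                paste0("ID=", t$tx_id, ";Parent=", g$gene_id)))
      ex <- ann$exons[ann$exons$tx_id == t$tx_id, , drop = FALSE]
      for (k in seq_len(nrow(ex)))
        lines <- c(lines, fmt_row(ex$chrom[k], "exon", ex$start[k], ex$end[k],
                                  t$strand, paste0("Parent=", t$tx_id)))
      for (cod in list(c("start_codon", "start_codons"),
                       c("stop_codon", "stop_codons"))) {
        cc <- ann[[cod[2]]]
        cc <- cc[cc$tx_id == t$tx_id, , drop = FALSE]
        for (k in seq_len(nrow(cc)))
          lines <- c(lines, fmt_row(t$chrom, cod[1], cc$start[k], cc$end[k],
                                    t$strand, paste0("Parent=", t$tx_id)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome to FASTA
#' @param genome a `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
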