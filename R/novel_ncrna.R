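#' Find novel (unannotated) transcribed loci
#'
#' A read cluster is a novel locus when none of its isoforms is associated
#' with an annotated gene. The locus representative is the longest member
#' read's transcript model.
#'
#' @param clusters list of `read_cluster` objects.
#' @param isoforms_by_locus named list (locus id ->  list of `isoform` with
#'   `gene_assoc` set).
#' @return list of `novel_locus` objects: `locus_id`, `chrom`, `strand`,
#'   `span`, `rep_read`, `rep_blocks`, `isoforms`.
#' @export
find_novel_loci <- function(clusters, isoforms_by_locus) {
  out <- list()
  for (cl in clusters) {
    isos <- isoforms_by_locus[[cl$locus_id]]
    if (is.null(isos) || length(isos) == 0L) next
    if (any(vapply(isos, function(i) length(i$gene_assoc) > 0L, logical(1))))
      next
    span_len <- vapply(cl$members, function(a)
      sum(a$blocks[, 2L] - a$blocks[, 1L]), integer(1))
    rep <- cl$members[[order(-span_len,
                             vapply(cl$members, `[[`, character(1),
                                    "qname"))[1]]]
    out[[length(out) + 1L]] <-
      structure(list(locus_id = cl$locus_id, chrom = cl$chrom,
                     strand = cl$strand, span = cl$span,
                     rep_read = rep$qname, rep_blocks = rep$blocks,
                     isoforms = isos),
                class = "novel_locus")
  }
  out
}

#' Longest open reading frame of a strand-oriented sequence
#'
#' Scans the three forward frames of the given sequence for ATG-to-stop
#' open reading frames; the returned length excludes the stop codon.
#' Sequences are assumed already oriented to the transcript strand.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @return list with `nt` (ORF length in nucleotides, 0 when none) and
#'   `aa` (amino acids, `nt / 3`).
#' @export
longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  chars <- strsplit(seq, "")[[1]]
  for (frame in 0:2) {
    i <- frame + 1L
    orf_start <- NA_integer_
    while (i + 2L <= n) {
      codon <- paste0(chars[i], chars[i + 1L], chars[i + 2L])
      if (is.na(orf_start)) {
        if (codon == "ATG") orf_start <- i
      } else if (codon %in% stops) {
        best <- max(best, i - orf_start)
        orf_start <- NA_integer_
      }
      i <- i + 3L
    }
    # an ORF reaching the sequence end without a stop is not counted: the
    # reading frame is open but the frame's coding length is undefined
  }
  list(nt = best, aa = best %/% 3L)
}

#' Classify a transcript as a lncRNA candidate
#'
#' Default rule: the transcript is at least 350 nt long and its longest ORF
#' is at most 100 amino acids. `variant = "orf200"` applies the alternative
#' rule of no ORF longer than 200 nt (without the length gate).
#'
#' @param seq strand-oriented transcript sequence.
#' @param variant `"aa100"` (default) or `"orf200"`.
#' @return logical.
#' @export
classify_lncrna <- function(seq, variant = c("aa100", "orf200")) {
  variant <- match.arg(variant)
  orf <- longest_orf(seq)
  if (variant == "aa100") nchar(seq) >= 350L && orf$aa <= 100L
  else orf$nt <= 200L
}

#' Flag fused and fragmented gene-model anomalies
#'
#' A transcript assembly spanning two or more annotated genes suggests the
#' annotation fragments one real gene (fused report, listing the bridged
#' gene sets); an annotated gene overlapped by two or more mutually
#' non-overlapping assemblies suggests the annotation entangles several
#' genes (fragmented report).
#'
#' @param isoforms list of `isoform` objects with `gene_assoc` and `exons`.
#' @return list with `fused` (data frame `iso_id`, `genes`) and
#'   `fragmented` (data frame `gene_id`, `n_assemblies`).
#' @export
flag_gene_model_anomalies <- function(isoforms) {
  fused <- list()
  per_gene <- list()
  for (iso in isoforms) {
    ga <- iso$gene_assoc
    if (length(ga) >= 2L)
      fused[[length(fused) + 1L]] <- data.frame(
        iso_id = iso$iso_id, genes = paste(ga, collapse = ","),
        stringsAsFactors = FALSE)
    for (g in ga) per_gene[[g]] <- c(per_gene[[g]], list(iso))
  }
  frag <- list()
  for (g in names(per_gene)) {
    isos <- per_gene[[g]]
    if (length(isos) < 2L) next
    spans <- t(vapply(isos, function(i)
      c(i$exons[1L, 1L], i$exons[nrow(i$exons), 2L]), integer(2)))
    disjoint <- FALSE
    for (i in seq_len(nrow(spans) - 1L)) for (j in (i + 1L):nrow(spans))
      if (spans[i, 2L] <= spans[j, 1L] || spans[j, 2L] <= spans[i, 1L])
        disjoint <- TRUE
    if (disjoint)
      frag[[length(frag) + 1L]] <- data.frame(
        gene_id = g, n_assemblies = length(isos), stringsAsFactors = FALSE)
  }
  list(fused = do.call(rbind, fused) %||%
         data.frame(iso_id = character(0), genes = character(0)),
       fragmented = do.call(rbind, frag) %||%
         data.frame(gene_id = character(0), n_assemblies = integer(0)))
}

#' Spliced sequence of an exon chain
#'
#' Concatenates exon sequences and orients the result to the transcript
#' strand.
#'
#' @param genome `DNAStringSet`.
#' @param chrom chromosome.
#' @param exons exon matrix (0-based half-open, sorted).
#' @param strand transcript strand.
#' @return character scalar.
#' @export
spliced_sequence <- function(genome, chrom, exons, strand = "+") {
  s <- paste(vapply(seq_len(nrow(exons)), function(i)
    seq_slice(genome, chrom, exons[i, 1L], exons[i, 2L]), character(1)),
    collapse = "")
  if (strand == "-") revcomp(s) else s
}
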