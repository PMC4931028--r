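#' Train a splice-junction scoring model from an annotation
#'
#' Position-weight matrices for the donor (3 exonic + 6 intronic nt) and
#' acceptor (14 intronic + 3 exonic nt) sites are estimated from all
#' annotated introns with +1 pseudocounts and converted to log-odds against
#' the background base frequencies of the training windows. The acceptance
#' threshold is the 5th percentile of the training-junction scores, so at
#' least 95% of annotated junctions pass by construction. Junctions must
#' additionally carry one of the canonical terminal dinucleotide pairs
#' (GT-AG, GC-AG, AT-AC).
#'
#' @param ann an `annotation_index` with at least `min_introns` introns.
#' @param genome `DNAStringSet`.
#' @param donor_exonic,donor_intronic,acceptor_intronic,acceptor_exonic
#'   window sizes in nucleotides.
#' @param min_introns minimum training introns (default 50).
#' @return a `junction_model` list with `donor_pwm`, `acceptor_pwm`
#'   (log-odds matrices), `bg`, `threshold`, `dinucs` and the window sizes.
#' @export
train_junction_model <- function(ann, genome, donor_exonic = 3L,
                                 donor_intronic = 6L, acceptor_intronic = 14L,
                                 acceptor_exonic = 3L, min_introns = 50L) {
  introns <- list()
  for (tx in unique(ann$exons$tx_id)) {
    ic <- transcript_introns(ann, tx)
    if (!nrow(ic)) next
    ch <- ann$transcripts$chrom[ann$transcripts$tx_id == tx][1]
    st <- ann$transcripts$strand[ann$transcripts$tx_id == tx][1]
    for (i in seq_len(nrow(ic)))
      introns[[length(introns) + 1L]] <- list(chrom = ch, start = ic[i, 1L],
                                              end = ic[i, 2L], strand = st)
  }
  # distinct introns only: shared junctions should not dominate training
  key <- vapply(introns, function(x)
    paste(x$chrom, x$start, x$end, x$strand), character(1))
  introns <- introns[!duplicated(key)]
  if (length(introns) < min_introns)
    stop("need at least ", min_introns, " distinct annotated introns, found ",
         length(introns))
  min_len <- donor_intronic + acceptor_intronic
  short <- vapply(introns, function(x) x$end - x$start < min_len, logical(1))
  if (any(short)) stop(sum(short), " intron(s) shorter than the model windows")

  win <- lapply(introns, function(x)
    junction_windows(genome, x$chrom, x$start, x$end, x$strand,
                     donor_exonic, donor_intronic,
                     acceptor_intronic, acceptor_exonic))
  dW <- donor_exonic + donor_intronic
  aW <- acceptor_intronic + acceptor_exonic
  dmat <- t(vapply(win, function(w) strsplit(w$donor, "")[[1]], character(dW)))
  amat <- t(vapply(win, function(w) strsplit(w$acceptor, "")[[1]], character(aW)))
  bases <- c("A", "C", "G", "T")
  bg <- table(factor(c(dmat, amat), levels = bases)) + 1
  bg <- as.numeric(bg / sum(bg)); names(bg) <- bases
  pwm <- function(m) {
    counts <- apply(m, 2L, function(col)
      table(factor(col, levels = bases)) + 1)
    p <- sweep(counts, 2L, colSums(counts), "/")
    log(p / bg)
  }
  model <- structure(list(donor_pwm = pwm(dmat), acceptor_pwm = pwm(amat),
                          bg = bg, threshold = NA_real_,
                          dinucs = c("GT-AG", "GC-AG", "AT-AC"),
                          donor_exonic = donor_exonic,
                          donor_intronic = donor_intronic,
                          acceptor_intronic = acceptor_intronic,
                          acceptor_exonic = acceptor_exonic),
                     class = "junction_model")
  scores <- vapply(introns, function(x)
    score_junction(model, genome,
                   genomic_interval(x$chrom, x$start, x$end, x$strand)),
    numeric(1))
  model$threshold <- unname(quantile(scores, 0.05, type = 1))
  model
}

# strand-oriented donor/acceptor windows of one intron
junction_windows <- function(genome, chrom, start, end, strand,
                             de = 3L, di = 6L, ai = 14L, ae = 3L) {
  if (strand == "+") {
    donor <- extract_sequence(genome, genomic_interval(chrom, start - de,
                                                       start + di, "+"))
    acceptor <- extract_sequence(genome, genomic_interval(chrom, end - ai,
                                                          end + ae, "+"))
  } else {
    donor <- extract_sequence(genome, genomic_interval(chrom, end - di,
                                                       end + de, "-"))
    acceptor <- extract_sequence(genome, genomic_interval(chrom, start - ae,
                                                          start + ai, "-"))
  }
  list(donor = donor, acceptor = acceptor)
}

#' Score one intron under a junction model
#'
#' @param model a `junction_model`.
#' @param genome `DNAStringSet`.
#' @param intron a [genomic_interval()] with a definite strand; windows are
#'   strand-oriented before scoring.
#' @return the summed donor + acceptor PWM log-odds score.
#' @export
score_junction <- function(model, genome, intron) {
  stopifnot(inherits(intron, "genomic_interval"), intron$strand %in% c("+", "-"))
  if (intron$end - intron$start < model$donor_intronic + model$acceptor_intronic)
    stop("intron shorter than the model windows")
  w <- junction_windows(genome, intron$chrom, intron$start, intron$end,
                        intron$strand, model$donor_exonic,
                        model$donor_intronic, model$acceptor_intronic,
                        model$acceptor_exonic)
  score_window(model$donor_pwm, w$donor) +
    score_window(model$acceptor_pwm, w$acceptor)
}

score_window <- function(pwm, seq) {
  chars <- strsplit(seq, "")[[1]]
  s <- 0
  for (j in seq_along(chars)) {
    b <- chars[j]
    if (b %in% rownames(pwm)) s <- s + pwm[b, j]  # N contributes 0
  }
  unname(s)
}

junction_dinucs <- function(genome, chrom, start, end, strand) {
  if (strand == "+") {
    d <- seq_slice(genome, chrom, start, start + 2L)
    a <- seq_slice(genome, chrom, end - 2L, end)
  } else {
    d <- revcomp(seq_slice(genome, chrom, end - 2L, end))
    a <- revcomp(seq_slice(genome, chrom, start, start + 2L))
  }
  paste0(d, "-", a)
}

#' Does one intron pass the junction filter?
#' @inheritParams score_junction
#' @return logical.
#' @export
junction_passes <- function(model, genome, intron) {
  dn <- junction_dinucs(genome, intron$chrom, intron$start, intron$end,
                        intron$strand)
  if (!dn %in% model$dinucs) return(FALSE)
  score_junction(model, genome, intron) >= model$threshold
}

#' Filter spliced alignments by splice-junction plausibility
#'
#' An alignment is rejected if any of its introns fails either the canonical
#' terminal-dinucleotide gate or the PWM score threshold (all-or-nothing,
#' read-level accounting). Unspliced alignments always pass. Introns are
#' scored on the alignment's strand.
#'
#' @param alignments list of `read_aln`.
#' @param model a `junction_model`.
#' @param genome `DNAStringSet`.
#' @return list with `kept` and `rejected` alignment lists.
#' @export
filter_alignments <- function(alignments, model, genome) {
  ok <- vapply(alignments, function(a) {
    ic <- aln_introns(a)
    if (!nrow(ic)) return(TRUE)
    for (i in seq_len(nrow(ic)))
      if (!junction_passes(model, genome,
                           genomic_interval(a$chrom, ic[i, 1L], ic[i, 2L],
                                            a$strand)))
        return(FALSE)
    TRUE
  }, logical(1))
  list(kept = alignments[ok], rejected = alignments[!ok])
}

#' Assign a transcript strand from poly(A)-tail evidence
#'
#' A trailing soft clip that is essentially poly(A) places the transcript on
#' the `+` genomic strand; a leading poly(T) clip places it on `-`. If an
#' upstream platform strand is supplied and contradicts the tail-derived
#' strand, or no tail evidence exists and no platform strand is known, the
#' read is unassignable and is dropped from isoform analysis.
#'
#' @param aln a `read_aln`.
#' @param platform_strand optional strand reported upstream (`"+"`, `"-"`,
#'   or `NA`).
#' @param min_tail minimum clip length considered a tail (default 5).
#' @param min_purity minimum A (or T) fraction of the clip (default 0.8).
#' @return `"+"`, `"-"` or `NA_character_` (unassignable).
#' @export
assign_strand <- function(aln, platform_strand = NA_character_,
                          min_tail = 5L, min_purity = 0.8) {
  base_frac <- function(s, b) {
    n <- nchar(s)
    if (n == 0L) return(0)
    (n - nchar(gsub(b, "", s, fixed = TRUE))) / n
  }
  plus <- nchar(aln$clip3) >= min_tail && base_frac(aln$clip3, "A") >= min_purity
  minus <- nchar(aln$clip5) >= min_tail && base_frac(aln$clip5, "T") >= min_purity
  tail_strand <- if (plus && !minus) "+" else if (minus && !plus) "-" else
    NA_character_
  if (!is.na(tail_strand)) {
    if (!is.na(platform_strand) && platform_strand != tail_strand)
      return(NA_character_)
    return(tail_strand)
  }
  if (!is.na(platform_strand)) return(platform_strand)
  NA_character_
}

#' Separate uniquely aligned reads from multi-mapping reads
#'
#' @param alignments list of `read_aln` with populated `n_hits`.
#' @return list with `unique` and `multi` alignment lists; multi-reads are
#'   excluded from isoform assembly but retained for reporting.
#' @export
partition_multimappers <- function(alignments) {
  multi <- vapply(alignments, function(a) a$n_hits > 1L, logical(1))
  list(unique = alignments[!multi], multi = alignments[multi])
}

#' Run the full alignment-filter cascade
#'
#' Applies junction filtering, then strand assignment, then multi-mapper
#' separation, and tallies the read-level cascade. Every input read lands in
#' exactly one terminal bin: kept-unique, multi, rejected-junction,
#' unassignable-strand, or unaligned.
#'
#' @param alignments list of `read_aln` (primary alignments).
#' @param model a `junction_model`.
#' @param genome `DNAStringSet`.
#' @param unaligned character vector of unaligned read ids.
#' @param platform_strands optional named strand vector per read id.
#' @return list with `kept` (stranded unique alignments, `tx_strand` set),
#'   `multi`, `rejected_junction`, `unassignable`, and `report` (a
#'   data frame with stage counts: aligned, junction_filtered, stranded,
#'   unique, multi).
#' @export
filter_cascade <- function(alignments, model, genome,
                           unaligned = character(0),
                           platform_strands = NULL) {
  jf <- filter_alignments(alignments, model, genome)
  stranded <- list(); unassignable <- list()
  for (a in jf$kept) {
    ps <- if (!is.null(platform_strands)) platform_strands[[a$qname]] %||%
      NA_character_ else NA_character_
    s <- assign_strand(a, ps)
    if (is.na(s)) unassignable[[length(unassignable) + 1L]] <- a
    else { a$tx_strand <- s; stranded[[length(stranded) + 1L]] <- a }
  }
  pm <- partition_multimappers(stranded)
  n_al <- length(alignments)
  report <- data.frame(
    stage = c("aligned", "junction_filtered", "stranded", "unique", "multi"),
    reads = c(n_al, length(jf$kept), length(stranded), length(pm$unique),
              length(pm$multi)))
  report$pct_of_aligned <- if (n_al > 0) round(100 * report$reads / n_al, 2)
                           else NA_real_
  list(kept = pm$unique, multi = pm$multi, rejected_junction = jf$rejected,
       unassignable = unassignable, unaligned = unaligned, report = report)
}
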