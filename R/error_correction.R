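#' Correct a long read against the reference genome
#'
#' Mismatched read bases are replaced by the reference base, inserted bases
#' are removed and deleted reference bases are re-inserted. When
#' `masking_enabled` is `TRUE`, edits whose reference footprint lies within
#' `junction_mask_width` nucleotides of a block boundary adjacent to an
#' intron gap are left uncorrected; this protects genuine splice-site signal
#' during the first correction round, when junction placement is still
#' uncertain. Soft-clipped sequence is never altered.
#'
#' @param aln a [read_aln()] for the read.
#' @param genome `DNAStringSet`.
#' @param junction_mask_width mask half-width in reference nucleotides
#'   (default 10).
#' @param masking_enabled apply the junction mask?
#' @return the corrected read sequence (character scalar) in the read's
#'   original orientation (reverse-complemented back for `-` alignments),
#'   clips included verbatim.
#' @export
correct_read <- function(aln, genome, junction_mask_width = 10L,
                         masking_enabled = FALSE) {
  stopifnot(junction_mask_width >= 0L)
  ed <- aln$edits
  if (nrow(ed)) {
    keep <- rep(TRUE, nrow(ed))
    if (masking_enabled && nrow(aln$blocks) > 1L) {
      nb <- nrow(aln$blocks)
      bnd <- c(aln$blocks[-nb, 2L] - 1L,  # last exonic base before each gap
               aln$blocks[-1L, 1L])       # first exonic base after each gap
      for (i in seq_len(nrow(ed))) {
        lo <- ed$ref_pos[i]
        hi <- ed$ref_pos[i] + max(ed$len[i] - 1L, 0L)
        d <- min(pmax(bnd - hi, lo - bnd, 0L))
        if (d <= junction_mask_width) keep[i] <- FALSE
      }
    }
    ed <- ed[keep, , drop = FALSE]
  }
  chars <- strsplit(aln$aligned_seq, "")[[1]]
  if (length(chars) < max(0L, max(c(0L, ed$read_off + ed$len * (ed$kind != "deletion")))))
    stop("edit operations inconsistent with read length")
  if (nrow(ed)) {
    # at equal read offsets, re-insert deleted bases only after substitutions
    # and insertion removals at that offset have been applied
    ed <- ed[order(-ed$read_off, ed$kind == "deletion"), , drop = FALSE]
    for (i in seq_len(nrow(ed))) {
      k <- ed$kind[i]; off <- ed$read_off[i]; len <- ed$len[i]
      if (k == "mismatch") {
        chars[(off + 1L):(off + len)] <-
          strsplit(seq_slice(genome, aln$chrom, ed$ref_pos[i],
                             ed$ref_pos[i] + len), "")[[1]]
      } else if (k == "insertion") {
        chars <- chars[-((off + 1L):(off + len))]
      } else {
        ins <- strsplit(seq_slice(genome, aln$chrom, ed$ref_pos[i],
                                  ed$ref_pos[i] + len), "")[[1]]
        chars <- append(chars, ins, after = off)
      }
    }
  }
  out <- paste0(aln$clip5, paste(chars, collapse = ""), aln$clip3)
  if (identical(aln$strand, "-")) revcomp(out) else out
}

#' Iterative alignment and error correction
#'
#' Alternates spliced alignment and reference-guided correction. The first
#' iteration corrects with junction masking enabled; subsequent iterations
#' correct everything. Reads are realigned after each correction round and
#' the final iteration's reads and alignments are returned.
#'
#' @param reads named character vector of read sequences.
#' @param genome `DNAStringSet`.
#' @param cfg an [aligner_config()].
#' @param n_iterations number of align/correct rounds (>= 1; default 2).
#' @param junction_mask_width passed to [correct_read()].
#' @return list with `reads` (corrected sequences), `alignments` (final
#'   realignment of the corrected reads) and `unaligned` read ids.
#' @export
iterate_correction <- function(reads, genome, cfg = aligner_config(),
                               n_iterations = 2L, junction_mask_width = 10L) {
  stopifnot(n_iterations >= 1L)
  cur <- reads
  res <- run_alignment(cur, genome, cfg)
  for (it in seq_len(n_iterations)) {
    masking <- it == 1L
    for (a in res$alignments)
      cur[[a$qname]] <- correct_read(a, genome, junction_mask_width, masking)
    res <- run_alignment(cur, genome, cfg)
  }
  list(reads = cur, alignments = res$alignments, unaligned = res$unaligned)
}

#' Estimate the per-nucleotide error profile of a set of alignments
#'
#' Rates use aligned reference nucleotides (sum of block widths over primary
#' alignments) as the shared denominator; insertions are counted by inserted
#' base and deletions by deleted reference base, so the total per-nucleotide
#' error is the sum of the three rates.
#'
#' @param alignments list of `read_aln` records (primary alignments).
#' @return an `error_profile` list: `mismatch_rate`, `insertion_rate`,
#'   `deletion_rate`, `total_rate`, `mean_insertion_len`,
#'   `mean_deletion_len`, `aligned_nt`.
#' @export
estimate_error_profile <- function(alignments) {
  stopifnot(length(alignments) > 0L)
  denom <- 0
  mm <- ins <- del <- 0
  ins_lens <- del_lens <- integer(0)
  for (a in alignments) {
    denom <- denom + sum(a$blocks[, 2L] - a$blocks[, 1L])
    ed <- a$edits
    if (!nrow(ed)) next
    mm <- mm + sum(ed$len[ed$kind == "mismatch"])
    il <- ed$len[ed$kind == "insertion"]; dl <- ed$len[ed$kind == "deletion"]
    ins <- ins + sum(il); del <- del + sum(dl)
    ins_lens <- c(ins_lens, il); del_lens <- c(del_lens, dl)
  }
  if (denom == 0) stop("zero aligned nucleotides")
  structure(list(mismatch_rate = mm / denom, insertion_rate = ins / denom,
                 deletion_rate = del / denom,
                 total_rate = (mm + ins + del) / denom,
                 mean_insertion_len = if (length(ins_lens)) mean(ins_lens) else NA_real_,
                 mean_deletion_len = if (length(del_lens)) mean(del_lens) else NA_real_,
                 aligned_nt = denom),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(paste0("<error_profile> total %.3f%% ",
                     "(mismatch %.3f%%, insertion %.3f%%, deletion %.3f%%) ",
                     "over %d aligned nt\n"),
              100 * x$total_rate, 100 * x$mismatch_rate,
              100 * x$insertion_rate, 100 * x$deletion_rate, x$aligned_nt))
  invisible(x)
}
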