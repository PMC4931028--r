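#' Spliced read alignment record
#'
#' The in-memory representation of one spliced alignment of a long read.
#' `aligned_seq` holds the read bases between the soft clips in *genomic*
#' orientation (as in a SAM record), including inserted bases; `clip5`/`clip3`
#' are the leading/trailing soft-clip sequences in the same orientation.
#' `edits` records every deviation from the reference:
#' \describe{
#'   \item{mismatch}{`ref_pos` is the mismatched reference base, `read_off`
#'     the 0-based offset of the read base within `aligned_seq`, `len = 1`.}
#'   \item{insertion}{`len` read bases at `read_off` that consume no
#'     reference; `ref_pos` is the reference position before which they sit.}
#'   \item{deletion}{`len` reference bases starting at `ref_pos` that are
#'     absent from the read; `read_off` is the offset of the next read base.}
#' }
#'
#' @param qname read id.
#' @param chrom chromosome.
#' @param strand aligner-reported strand, `"+"` or `"-"`.
#' @param blocks integer matrix (columns `start`, `end`; 0-based half-open)
#'   of aligned blocks, sorted, non-overlapping; gaps between blocks are
#'   introns.
#' @param aligned_seq read bases between clips, genomic orientation.
#' @param edits data frame with columns `kind`, `ref_pos`, `read_off`, `len`
#'   (may have zero rows).
#' @param clip5,clip3 soft-clip sequences (possibly `""`).
#' @param n_hits number of genomic locations the read aligns to.
#' @param tx_strand transcript strand once assigned (`"+"`, `"-"` or `"*"`).
#' @return a `read_aln` object.
#' @export
read_aln <- function(qname, chrom, strand, blocks, aligned_seq,
                     edits = empty_edits(), clip5 = "", clip3 = "",
                     n_hits = 1L, tx_strand = "*") {
  storage.mode(blocks) <- "integer"
  colnames(blocks) <- c("start", "end")
  if (nrow(blocks) > 1L &&
      any(blocks[-1L, 1L] < blocks[-nrow(blocks), 2L]))
    stop("alignment blocks must be sorted and non-overlapping")
  if (nrow(blocks) > 1L && any(blocks[-1L, 1L] - blocks[-nrow(blocks), 2L] < 1L))
    stop("intron gaps must be >= 1 nt")
  structure(list(qname = qname, chrom = chrom, strand = strand,
                 blocks = blocks, aligned_seq = aligned_seq, edits = edits,
                 clip5 = clip5, clip3 = clip3, n_hits = as.integer(n_hits),
                 tx_strand = tx_strand),
            class = "read_aln")
}

#' @export
print.read_aln <- function(x, ...) {
  cat(sprintf("<read_aln> %s %s:%d-%d(%s) blocks=%d edits=%d clips=%d/%d hits=%d\n",
              x$qname, x$chrom, aln_start(x), aln_end(x), x$strand,
              nrow(x$blocks), nrow(x$edits), nchar(x$clip5), nchar(x$clip3),
              x$n_hits))
  invisible(x)
}

empty_edits <- function()
  data.frame(kind = character(0), ref_pos = integer(0),
             read_off = integer(0), len = integer(0))

aln_start <- function(aln) aln$blocks[1L, 1L]
aln_end <- function(aln) aln$blocks[nrow(aln$blocks), 2L]
aln_introns <- function(aln) introns_from_exons(aln$blocks)

#' Reconstruct the CIGAR string of an alignment record
#' @param aln a `read_aln`.
#' @return CIGAR using `=`, `X`, `I`, `D`, `N`, `S` operations.
#' @export
aln_cigar <- function(aln) {
  ops <- character(0)
  push <- function(n, op) if (n > 0L) ops[[length(ops) + 1L]] <<- paste0(n, op)
  if (nchar(aln$clip5)) push(nchar(aln$clip5), "S")
  ed <- aln$edits[order(aln$edits$ref_pos, aln$edits$read_off), , drop = FALSE]
  for (b in seq_len(nrow(aln$blocks))) {
    bs <- aln$blocks[b, 1L]; be <- aln$blocks[b, 2L]
    if (b > 1L) push(bs - aln$blocks[b - 1L, 2L], "N")
    is_ins <- ed$kind == "insertion"
    in_blk <- ed[(!is_ins & ed$ref_pos >= bs & ed$ref_pos < be) |
                 (is_ins & (ed$ref_pos > bs | b == 1L) & ed$ref_pos <= be),
                 , drop = FALSE]
    cur <- bs
    for (i in seq_len(nrow(in_blk))) {
      e <- in_blk[i, ]
      push(e$ref_pos - cur, "=")
      if (e$kind == "mismatch") { push(e$len, "X"); cur <- e$ref_pos + e$len }
      else if (e$kind == "insertion") { push(e$len, "I"); cur <- e$ref_pos }
      else { push(e$len, "D"); cur <- e$ref_pos + e$len }
    }
    push(be - cur, "=")
  }
  if (nchar(aln$clip3)) push(nchar(aln$clip3), "S")
  paste(ops, collapse = "")
}

#' Write alignment records as SAM
#'
#' Introns are encoded as `N` operations and soft clips as `S`; sequence is
#' emitted in genomic orientation per the SAM convention.
#'
#' @param alns list of `read_aln` records.
#' @param genome `DNAStringSet` used for the header `@SQ` lines.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alns, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  rec <- vapply(alns, function(a) {
    flag <- if (identical(a$strand, "-")) 16L else 0L
    seq <- paste0(a$clip5, a$aligned_seq, a$clip3)
    paste(a$qname, flag, a$chrom, aln_start(a) + 1L, 60L, aln_cigar(a),
          "*", 0L, 0L, seq, "*", paste0("NH:i:", a$n_hits), sep = "\t")
  }, character(1))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read spliced alignments from SAM or BAM
#'
#' Primary alignments are parsed into `read_aln` records; multiplicity is the
#' `NH` tag when present, otherwise 1 + the number of secondary records for
#' the read. `M` CIGAR operations are resolved into match/mismatch against
#' the genome; `=`/`X` operations are used directly. Unaligned records are
#' returned separately by id.
#'
#' @param path SAM or BAM file.
#' @param genome `DNAStringSet` (needed to resolve `M` operations).
#' @return list with `alignments` (list of `read_aln`) and `unaligned`
#'   (character vector of read ids).
#' @export
read_sam <- function(path, genome) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NH")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0L) return(list(alignments = list(), unaligned = character(0)))
  flag <- x$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  sec_counts <- table(x$qname[secondary & !unmapped])
  keep <- which(!unmapped & !secondary & !supplementary)
  alns <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    chrom <- as.character(x$rname[k])
    if (!chrom %in% names(genome))
      stop("SAM record references unknown chromosome: ", chrom)
    nh <- x$tag$NH[k]
    n_hits <- if (!is.null(nh) && !is.na(nh)) as.integer(nh) else
      1L + as.integer(sec_counts[x$qname[k]] %||% 0L)
    if (is.na(n_hits)) n_hits <- 1L
    alns[[i]] <- parse_sam_record(
      qname = x$qname[k],
      chrom = chrom,
      strand = if (bitwAnd(flag[k], 16L) != 0L) "-" else "+",
      pos0 = x$pos[k] - 1L,
      cigar = x$cigar[k],
      seq = as.character(x$seq[k]),
      genome = genome, n_hits = n_hits)
  }
  list(alignments = alns,
       unaligned = unique(x$qname[unmapped]))
}

parse_sam_record <- function(qname, chrom, strand, pos0, cigar, seq, genome,
                             n_hits = 1L) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  rpos <- pos0          # reference cursor
  qpos <- 0L            # read cursor (0-based, genomic orientation)
  clip5 <- ""; clip3 <- ""
  blocks <- list(); blk_start <- rpos
  edits <- list()
  aligned_from <- NA_integer_
  ref_chars <- NULL
  for (i in seq_along(ops)) {
    op <- ops[i]; ln <- lens[i]
    if (op == "S") {
      if (is.na(aligned_from)) clip5 <- substr(seq, qpos + 1L, qpos + ln)
      else clip3 <- substr(seq, qpos + 1L, qpos + ln)
      qpos <- qpos + ln
    } else if (op == "H") {
      # hard clip: no sequence present
    } else if (op %in% c("M", "=", "X")) {
      if (is.na(aligned_from)) aligned_from <- qpos
      if (op == "X" || op == "M") {
        rseg <- strsplit(seq_slice(genome, chrom, rpos, rpos + ln), "")[[1]]
        qseg <- strsplit(substr(seq, qpos + 1L, qpos + ln), "")[[1]]
        mm <- if (op == "X") seq_len(ln) else which(rseg != qseg & qseg != "N")
        for (m in mm)
          edits[[length(edits) + 1L]] <- list(kind = "mismatch",
                                              ref_pos = rpos + m - 1L,
                                              read_off = qpos + m - 1L,
                                              len = 1L)
      }
      rpos <- rpos + ln; qpos <- qpos + ln
    } else if (op == "I") {
      if (is.na(aligned_from)) aligned_from <- qpos
      edits[[length(edits) + 1L]] <- list(kind = "insertion", ref_pos = rpos,
                                          read_off = qpos, len = ln)
      qpos <- qpos + ln
    } else if (op == "D") {
      edits[[length(edits) + 1L]] <- list(kind = "deletion", ref_pos = rpos,
                                          read_off = qpos, len = ln)
      rpos <- rpos + ln
    } else if (op == "N") {
      blocks[[length(blocks) + 1L]] <- c(blk_start, rpos)
      rpos <- rpos + ln
      blk_start <- rpos
    } else stop("unsupported CIGAR op: ", op)
  }
  blocks[[length(blocks) + 1L]] <- c(blk_start, rpos)
  bm <- do.call(rbind, blocks)
  colnames(bm) <- c("start", "end")
  ed <- if (length(edits)) do.call(rbind, lapply(edits, as.data.frame)) else
    empty_edits()
  aligned_from <- if (is.na(aligned_from)) nchar(clip5) else aligned_from
  aligned_len <- nchar(seq) - nchar(clip5) - nchar(clip3)
  aligned_seq <- substr(seq, nchar(clip5) + 1L, nchar(clip5) + aligned_len)
  if (nrow(ed)) ed$read_off <- ed$read_off - nchar(clip5)
  read_aln(qname, chrom, strand, bm, aligned_seq, ed, clip5, clip3, n_hits)
}

#' Configuration for the external spliced aligner
#'
#' The default command template targets minimap2's spliced preset with
#' `=`/`X` CIGAR output; any spliced aligner that emits SAM with `N`
#' operations for introns and `S` for soft clips can be substituted (e.g., a
#' GMAP invocation). Placeholders `{genome}`, `{reads}`, `{out}`,
#' `{max_intron}` and `{threads}` are expanded at run time.
#'
#' @param command command template; must write SAM to `{out}`.
#' @param max_intron maximum intron length; typically the annotation's
#'   largest intron.
#' @param threads worker threads passed to the aligner.
#' @return an `aligner_config` list.
#' @export
aligner_config <- function(command = paste(
                             "minimap2 -a -x splice --eqx -u f -C 5",
                             "-G {max_intron} -t {threads}",
                             "-o {out} {genome} {reads}"),
                           max_intron = 10000L, threads = 1L) {
  structure(list(command = command, max_intron = as.integer(max_intron),
                 threads = as.integer(threads)),
            class = "aligner_config")
}

#' Align long reads with the external spliced aligner
#'
#' Writes the reads and genome to temporary FASTA files, runs the configured
#' aligner command and parses the resulting SAM into `read_aln` records.
#'
#' @param reads named character vector (or data frame with `id`, `seq`) of
#'   read sequences.
#' @param genome `DNAStringSet`.
#' @param cfg an [aligner_config()].
#' @return list with `alignments` and `unaligned`, as [read_sam()].
#' @export
run_alignment <- function(reads, genome, cfg = aligner_config()) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$id)
  if (length(reads) == 0L) return(list(alignments = list(),
                                       unaligned = character(0)))
  gpath <- tempfile(fileext = ".fa")
  rpath <- tempfile(fileext = ".fa")
  opath <- tempfile(fileext = ".sam")
  on.exit(unlink(c(gpath, rpath, opath)), add = TRUE)
  write_genome_fasta(genome, gpath)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), rpath)
  cmd <- cfg$command
  cmd <- gsub("{genome}", gpath, cmd, fixed = TRUE)
  cmd <- gsub("{reads}", rpath, cmd, fixed = TRUE)
  cmd <- gsub("{out}", opath, cmd, fixed = TRUE)
  cmd <- gsub("{max_intron}", as.character(cfg$max_intron), cmd, fixed = TRUE)
  cmd <- gsub("{threads}", as.character(cfg$threads), cmd, fixed = TRUE)
  err <- tempfile()
  status <- system(paste(cmd, "2>", shQuote(err)))
  if (status != 0L)
    stop("aligner failed (exit ", status, "): ",
         paste(readLines(err, warn = FALSE), collapse = "\n"))
  res <- read_sam(opath, genome)
  seen <- c(vapply(res$alignments, `[[`, character(1), "qname"), res$unaligned)
  res$unaligned <- union(res$unaligned, setdiff(names(reads), seen))
  res
}
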