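#' Parameters for the synthetic Iso-Seq data generator
#'
#' The defaults emulate the study conditions the pipeline targets:
#' multi-exon genes with canonical (GT..AG, extended consensus) splice
#' sites, planted alternative-splicing isoforms withheld from the
#' annotation, several poly(A) sites per gene with an AATAAA signal planted
#' 25 nt upstream of most cleavage sites, per-nucleotide read error rates
#' of 0.64% mismatch / 1.07% insertion / 0.63% deletion with geometric
#' indel lengths of mean 1.23 (insertion) and 1.16 (deletion), and a +/-2 nt
#' cleavage-position jitter that exercises microheterogeneity merging.
#'
#' @param seed mandatory RNG seed.
#' @param n_genes number of annotated genes.
#' @param exons_per_gene integer range c(min, max).
#' @param exon_len,intron_len exon/intron length ranges in nt.
#' @param as_events named counts of alternative-splicing events to plant
#'   (one event per gene, types `intron_retention`, `exon_skipping`,
#'   `alt_5prime`, `alt_3prime`); their isoforms are withheld from the
#'   annotation.
#' @param polya_sites_per_gene range of poly(A) sites per gene.
#' @param polya_spacing spacing between planted sites in nt.
#' @param polya_weight_major weight of the 3'-most site when a gene has
#'   several (the rest share the remainder equally).
#' @param reads_per_isoform range of reads per isoform.
#' @param mismatch_rate,insertion_rate,deletion_rate per-nucleotide error
#'   rates.
#' @param mean_ins_len,mean_del_len mean indel event lengths.
#' @param tail_len poly(A) tail length range.
#' @param frac_untailed fraction of reads emitted without a tail (these
#'   cannot be stranded downstream).
#' @param frac_truncated fraction of reads with a random 5' truncation
#'   (non-full-length reads).
#' @param end_jitter cleavage-position jitter half-width in nt.
#' @param motif,motif_offset,motif_frac polyadenylation signal planted at
#'   `motif_offset` (match start relative to the cleavage site) in a
#'   `motif_frac` fraction of sites.
#' @param utr5_len,utr3_len UTR lengths flanking the planted CDS.
#' @param frac_minus_strand fraction of genes on the `-` strand.
#' @param n_novel_loci unannotated single-exon transcribed loci.
#' @param novel_locus_len their length in nt.
#' @param intergenic_gap spacing between loci in nt.
#' @param duplicate_gene also copy gene 1's genomic sequence into an
#'   intergenic location, making its reads multi-mappers.
#' @return a `sim_params` list.
#' @export
sim_params <- function(seed,
                       n_genes = 20L,
                       exons_per_gene = c(3L, 6L),
                       exon_len = c(120L, 300L),
                       intron_len = c(80L, 400L),
                       as_events = c(intron_retention = 3L,
                                     exon_skipping = 2L,
                                     alt_5prime = 1L, alt_3prime = 1L),
                       polya_sites_per_gene = c(1L, 3L),
                       polya_spacing = 50L,
                       polya_weight_major = 0.6,
                       reads_per_isoform = c(5L, 8L),
                       mismatch_rate = 0.0064,
                       insertion_rate = 0.0107,
                       deletion_rate = 0.0063,
                       mean_ins_len = 1.23,
                       mean_del_len = 1.16,
                       tail_len = c(15L, 40L),
                       frac_untailed = 0,
                       frac_truncated = 0,
                       end_jitter = 2L,
                       motif = "AATAAA",
                       motif_offset = -25L,
                       motif_frac = 0.8,
                       utr5_len = 60L,
                       utr3_len = 160L,
                       frac_minus_strand = 0.5,
                       n_novel_loci = 0L,
                       novel_locus_len = 600L,
                       intergenic_gap = 500L,
                       duplicate_gene = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  rates <- c(mismatch_rate, insertion_rate, deletion_rate)
  stopifnot(all(rates >= 0), all(rates < 1), polya_spacing > 0L,
            intergenic_gap > 0L)
  p <- as.list(environment())
  structure(p, class = "sim_params")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# plant `s` into chars at 0-based offset
plant <- function(chars, off, s) {
  repl <- strsplit(s, "")[[1]]
  chars[(off + 1L):(off + length(repl))] <- repl
  chars
}

# extended splice-site consensus planted at every simulated junction:
# ...CAG | GTAAGT ...... TTCTTTTTTTTCAG | GTT...
# (3 exonic + 6 intronic donor nt; 14 intronic + 3 exonic acceptor nt)
DONOR_EXON <- "CAG"
DONOR_INTRON <- "GTAAGT"
ACCEPTOR_INTRON <- "TTCTTTTTTTTCAG"
ACCEPTOR_EXON <- "GTT"

plant_donor <- function(chars, intron_start)
  plant(plant(chars, intron_start - 3L, DONOR_EXON), intron_start,
        DONOR_INTRON)
plant_acceptor <- function(chars, intron_end)
  plant(plant(chars, intron_end - 14L, ACCEPTOR_INTRON), intron_end,
        ACCEPTOR_EXON)

local_to_genomic <- function(block, g0, glen, strand) {
  if (strand == "+") c(g0 + block[1L], g0 + block[2L])
  else c(g0 + glen - block[2L], g0 + glen - block[1L])
}

map_exons <- function(ex_local, g0, glen, strand) {
  m <- t(apply(ex_local, 1L, local_to_genomic, g0 = g0, glen = glen,
               strand = strand))
  m <- m[order(m[, 1L]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  storage.mode(m) <- "integer"
  m
}

#' Simulate a toy genome, annotation and planted transcript structures
#'
#' Genes are placed non-overlapping on one chromosome with extended
#' consensus splice sites at every planted intron. Each gene carries a base
#' isoform (the only one present in the returned annotation) and, where an
#' AS event is planted, one alternative isoform differing by exactly that
#' event; poly(A) sites sit in the 3' UTR with the polyadenylation signal
#' planted upstream of most of them. Optional unannotated loci provide
#' novel-gene test cases.
#'
#' @param params a [sim_params()].
#' @return a `sim_truth` list: `genome` (`DNAStringSet`), `annotation`
#'   (`annotation_index`), `isoforms` (list with genomic exon/intron chains
#'   and planted event labels), `events` (data frame in
#'   [classify_events()] layout plus `gene_id`), `polya_sites` (data
#'   frame), `novel_loci` (data frame), `genes` (placement table) and
#'   `params`.
#' @export
simulate_genome <- function(params) {
  set.seed(params$seed)
  chrom <- "chr1"
  ev_plan <- rep(names(params$as_events), times = params$as_events)
  if (length(ev_plan) > params$n_genes)
    stop("more planted events than genes")
  ev_plan <- c(ev_plan, rep(NA_character_, params$n_genes - length(ev_plan)))

  pieces <- character(0)
  cursor <- 0L
  add_piece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }
  add_piece(rand_seq(params$intergenic_gap))

  genes <- list(); isoforms <- list(); events <- list(); polya <- list()
  ann_exons <- list(); ann_tx <- list(); ann_genes <- list()
  ann_starts <- list(); ann_stops <- list()

  for (gi in seq_len(params$n_genes)) {
    gene_id <- pad_id("SYNG", gi)
    strand <- if (runif(1) < params$frac_minus_strand) "-" else "+"
    ev <- ev_plan[gi]
    n_ex <- sample(params$exons_per_gene[1]:params$exons_per_gene[2], 1L)
    if (!is.na(ev)) n_ex <- max(n_ex, 3L)
    ex_len <- sample(params$exon_len[1]:params$exon_len[2], n_ex,
                     replace = TRUE)
    ex_len[1] <- max(ex_len[1], params$utr5_len + 60L)
    ex_len[n_ex] <- max(ex_len[n_ex], params$utr3_len + 60L)
    in_len <- sample(params$intron_len[1]:params$intron_len[2],
                     max(n_ex - 1L, 0L), replace = TRUE)
    glen <- sum(ex_len) + sum(in_len)
    # local (transcript-orientation) exon layout
    ex_local <- matrix(0L, n_ex, 2L)
    p <- 0L
    for (k in seq_len(n_ex)) {
      ex_local[k, ] <- c(p, p + ex_len[k])
      p <- p + ex_len[k] + if (k < n_ex) in_len[k] else 0L
    }
    chars <- strsplit(rand_seq(glen), "")[[1]]
    for (k in seq_len(n_ex - 1L)) {
      chars <- plant_donor(chars, ex_local[k, 2L])
      chars <- plant_acceptor(chars, ex_local[k + 1L, 1L])
    }
    # CDS anchors (transcript-space offsets mapped into exon 1 / last exon)
    start_local <- ex_local[1L, 1L] + params$utr5_len
    stop_local <- ex_local[n_ex, 2L] - params$utr3_len - 3L
    chars <- plant(chars, start_local, "ATG")
    chars <- plant(chars, stop_local, "TAA")

    # planted poly(A) sites (local coords, 3'-most first), within the 3' UTR
    n_sites <- sample(params$polya_sites_per_gene[1]:
                        params$polya_sites_per_gene[2], 1L)
    site_local <- ex_local[n_ex, 2L] - 4L -
      (seq_len(n_sites) - 1L) * params$polya_spacing
    if (any(site_local <= stop_local + 3L + params$end_jitter))
      stop("3' UTR too short for the requested poly(A) sites")
    has_motif <- runif(n_sites) < params$motif_frac
    for (s in seq_len(n_sites)) if (has_motif[s])
      chars <- plant(chars, site_local[s] + params$motif_offset, params$motif)
    w <- if (n_sites == 1L) 1 else
      c(params$polya_weight_major,
        rep((1 - params$polya_weight_major) / (n_sites - 1L), n_sites - 1L))

    # alternative isoform for the planted event (local coordinates)
    base_ex <- ex_local
    alt_ex <- NULL
    # the shift clears the 14-nt acceptor window of the base junction so the
    # two planted consensus contexts never overwrite each other
    delta <- 18L
    if (!is.na(ev)) {
      if (ev == "intron_retention") {
        # retain the 3'-most intron: retaining the 5'-most would make the
        # variant's intron chain a 3'-terminal suffix of the base chain,
        # which the collapsing rules fold back into the base isoform
        alt_ex <- rbind(ex_local[seq_len(n_ex - 2L), , drop = FALSE],
                        c(ex_local[n_ex - 1L, 1L], ex_local[n_ex, 2L]))
      } else if (ev == "exon_skipping") {
        alt_ex <- ex_local[-2L, , drop = FALSE]
      } else if (ev == "alt_5prime") {
        alt_ex <- ex_local
        alt_ex[1L, 2L] <- alt_ex[1L, 2L] - delta
        chars <- plant_donor(chars, alt_ex[1L, 2L])
      } else if (ev == "alt_3prime") {
        alt_ex <- ex_local
        alt_ex[2L, 1L] <- alt_ex[2L, 1L] + delta
        chars <- plant_acceptor(chars, alt_ex[2L, 1L])
      }
    }

    gseq <- paste(chars, collapse = "")
    g0 <- cursor
    add_piece(if (strand == "-") revcomp(gseq) else gseq)
    add_piece(rand_seq(params$intergenic_gap))

    loc2gen <- function(pos_local) {
      if (strand == "+") g0 + pos_local else g0 + glen - 1L - pos_local
    }
    ex_gen <- map_exons(base_ex, g0, glen, strand)
    genes[[gi]] <- data.frame(gene_id = gene_id, chrom = chrom,
                              start = g0, end = g0 + glen, strand = strand,
                              glen = glen, event = ev %||% NA_character_,
                              stringsAsFactors = FALSE)
    iso_base_id <- paste0(gene_id, ".1")
    isoforms[[length(isoforms) + 1L]] <-
      list(iso_id = iso_base_id, gene_id = gene_id, chrom = chrom,
           strand = strand, exons = ex_gen,
           introns = introns_from_exons(ex_gen), event = NA_character_)
    if (!is.null(alt_ex)) {
      alt_gen <- map_exons(alt_ex, g0, glen, strand)
      isoforms[[length(isoforms) + 1L]] <-
        list(iso_id = paste0(gene_id, ".2"), gene_id = gene_id,
             chrom = chrom, strand = strand, exons = alt_gen,
             introns = introns_from_exons(alt_gen), event = ev)
      events[[length(events) + 1L]] <-
        planted_event_row(ev, chrom, strand, base_ex, alt_ex, g0, glen,
                          gene_id)
    }
    polya[[length(polya) + 1L]] <- data.frame(
      gene_id = gene_id, chrom = chrom, strand = strand,
      pos = vapply(site_local, loc2gen, numeric(1)),
      pos_local = site_local, weight = w, has_motif = has_motif,
      stringsAsFactors = FALSE)

    tx_id <- iso_base_id
    ann_genes[[gi]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                  start = g0, end = g0 + glen,
                                  strand = strand, stringsAsFactors = FALSE)
    ann_tx[[gi]] <- data.frame(tx_id = tx_id, gene_id = gene_id,
                               chrom = chrom, start = g0, end = g0 + glen,
                               strand = strand, stringsAsFactors = FALSE)
    ann_exons[[gi]] <- data.frame(tx_id = tx_id, chrom = chrom,
                                  start = ex_gen[, 1L], end = ex_gen[, 2L],
                                  strand = strand, stringsAsFactors = FALSE)
    sc <- sort(c(loc2gen(start_local), loc2gen(start_local + 2L)))
    pc <- sort(c(loc2gen(stop_local), loc2gen(stop_local + 2L)))
    ann_starts[[gi]] <- data.frame(tx_id = tx_id, start = sc[1], end = sc[2] + 1L,
                                   strand = strand, stringsAsFactors = FALSE)
    ann_stops[[gi]] <- data.frame(tx_id = tx_id, start = pc[1], end = pc[2] + 1L,
                                  strand = strand, stringsAsFactors = FALSE)
  }

  novel <- list()
  for (ni in seq_len(params$n_novel_loci)) {
    strand <- if (runif(1) < params$frac_minus_strand) "-" else "+"
    len <- params$novel_locus_len
    g0 <- cursor
    add_piece(rand_seq(len))
    add_piece(rand_seq(params$intergenic_gap))
    site <- if (strand == "+") g0 + len - 4L else g0 + 3L
    novel[[ni]] <- data.frame(locus_id = pad_id("NOV", ni), chrom = chrom,
                              start = g0, end = g0 + len, strand = strand,
                              polya_pos = site, stringsAsFactors = FALSE)
  }

  if (isTRUE(params$duplicate_gene)) {
    gfirst <- genes[[1]]
    dup <- seq_slice_chars(pieces, gfirst$start, gfirst$end)
    add_piece(dup)
    add_piece(rand_seq(params$intergenic_gap))
  }
  add_piece(rand_seq(200L))

  genome <- Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""),
                                              chrom))
  ann <- new_annotation_index(
    do.call(rbind, ann_genes), do.call(rbind, ann_tx),
    do.call(rbind, ann_exons), do.call(rbind, ann_starts),
    do.call(rbind, ann_stops))
  ev_df <- do.call(rbind, events) %||%
    data.frame(type = character(0), chrom = character(0),
               strand = character(0), coord1 = integer(0),
               coord2 = integer(0), shared = integer(0),
               gene_id = character(0))
  structure(list(genome = genome, annotation = ann,
                 genes = do.call(rbind, genes), isoforms = isoforms,
                 events = ev_df, polya_sites = do.call(rbind, polya),
                 novel_loci = do.call(rbind, novel) %||%
                   data.frame(locus_id = character(0)),
                 params = params),
            class = "sim_truth")
}

# extract [start, end) from the accumulated genome pieces
seq_slice_chars <- function(pieces, start, end) {
  s <- paste(pieces, collapse = "")
  substr(s, start + 1L, end)
}

# genomic-coordinate event row for a planted alternative isoform
planted_event_row <- function(ev, chrom, strand, base_ex, alt_ex, g0, glen,
                              gene_id) {
  l2g <- function(x) if (strand == "+") g0 + x else g0 + glen - x
  if (ev == "intron_retention") {
    n <- nrow(base_ex)
    i <- c(base_ex[n - 1L, 2L], base_ex[n, 1L])
    gg <- sort(c(l2g(i[1]), l2g(i[2])))
    data.frame(type = ev, chrom = chrom, strand = strand, coord1 = gg[1],
               coord2 = gg[2], shared = NA_integer_, gene_id = gene_id)
  } else if (ev == "exon_skipping") {
    e <- base_ex[2L, ]
    gg <- sort(c(l2g(e[1]), l2g(e[2])))
    data.frame(type = ev, chrom = chrom, strand = strand, coord1 = gg[1],
               coord2 = gg[2], shared = NA_integer_, gene_id = gene_id)
  } else if (ev == "alt_5prime") {
    d <- sort(c(l2g(base_ex[1L, 2L]), l2g(alt_ex[1L, 2L])))
    data.frame(type = ev, chrom = chrom, strand = strand, coord1 = d[1],
               coord2 = d[2], shared = l2g(base_ex[2L, 1L]),
               gene_id = gene_id)
  } else {
    a <- sort(c(l2g(base_ex[2L, 1L]), l2g(alt_ex[2L, 1L])))
    data.frame(type = ev, chrom = chrom, strand = strand, coord1 = a[1],
               coord2 = a[2], shared = l2g(base_ex[1L, 2L]),
               gene_id = gene_id)
  }
}

#' Simulate error-bearing long reads from planted transcripts
#'
#' Each read is the spliced transcript sequence up to its chosen poly(A)
#' cleavage site (jittered by up to `end_jitter` nt) plus a non-genomic
#' poly(A) tail; per-nucleotide mismatches, insertions and deletions are
#' injected at the configured rates with geometric event lengths, and every
#' injected error, chosen site and tail length is recorded in the truth
#' table. The matching true alignment (`read_aln`) of every read is
#' emitted alongside, so downstream stages can be exercised and validated
#' without running an aligner.
#'
#' @param sim a `sim_truth` from [simulate_genome()].
#' @param params the same [sim_params()] (defaults to `sim$params`).
#' @return list with `reads` (named character vector), `alignments` (list
#'   of true `read_aln`), `truth` (per-read data frame) and
#'   `site_counts` (realized reads per planted poly(A) site).
#' @export
simulate_reads <- function(sim, params = sim$params) {
  set.seed(params$seed + 1L)
  genome <- sim$genome
  reads <- character(0)
  alns <- list()
  truth <- list()
  site_counts <- sim$polya_sites
  site_counts$n_reads <- 0L
  ridx <- 0L

  emit_read <- function(gene_id, iso, blocks_gen, strand, site_gen,
                        tail_len, n_hits) {
    ridx <<- ridx + 1L
    rid <- pad_id("read", ridx, width = 6L)
    injected <- inject_errors(genome, iso$chrom, blocks_gen, params)
    tail <- strrep("A", tail_len)
    if (strand == "+") {
      read_seq <- paste0(injected$seq, tail)
      clip5 <- ""; clip3 <- tail
    } else {
      read_seq <- paste0(revcomp(injected$seq), tail)
      clip5 <- strrep("T", tail_len); clip3 <- ""
    }
    reads[rid] <<- read_seq
    alns[[length(alns) + 1L]] <<-
      read_aln(rid, iso$chrom, strand, blocks_gen, injected$seq,
               injected$edits, clip5, clip3, n_hits = n_hits)
    truth[[length(truth) + 1L]] <<- data.frame(
      read_id = rid, gene_id = gene_id, iso_id = iso$iso_id,
      strand = strand, site_pos = site_gen, tail_len = tail_len,
      n_mismatch = sum(injected$edits$len[injected$edits$kind == "mismatch"]),
      n_ins = sum(injected$edits$len[injected$edits$kind == "insertion"]),
      n_del = sum(injected$edits$len[injected$edits$kind == "deletion"]),
      stringsAsFactors = FALSE)
    invisible(rid)
  }

  for (iso in sim$isoforms) {
    g <- sim$genes[sim$genes$gene_id == iso$gene_id, ]
    sites <- sim$polya_sites[sim$polya_sites$gene_id == iso$gene_id, ]
    n_reads <- sample(params$reads_per_isoform[1]:params$reads_per_isoform[2],
                      1L)
    n_hits <- if (isTRUE(params$duplicate_gene) &&
                  iso$gene_id == sim$genes$gene_id[1]) 2L else 1L
    for (r in seq_len(n_reads)) {
      si <- sample.int(nrow(sites), 1L, prob = sites$weight)
      jit <- sample(seq(-params$end_jitter, params$end_jitter), 1L)
      site_local <- sites$pos_local[si] + jit
      # local exon chain trimmed at the cleavage site (3' UTR lives in the
      # last exon, shared by all planted isoforms of the gene)
      ex_local <- genomic_to_local_exons(iso$exons, g$start, g$glen,
                                         g$strand)
      ex_local[nrow(ex_local), 2L] <- site_local + 1L
      trunc5 <- 0L
      if (runif(1) < params$frac_truncated) {
        tx_len <- sum(ex_local[, 2L] - ex_local[, 1L])
        trunc5 <- sample.int(max(tx_len %/% 3L, 1L), 1L)
        ex_local <- truncate_5prime(ex_local, trunc5)
      }
      blocks_gen <- map_exons(ex_local, g$start, g$glen, g$strand)
      tail_len <- if (runif(1) < params$frac_untailed) 0L else
        sample(params$tail_len[1]:params$tail_len[2], 1L)
      site_gen <- if (g$strand == "+") g$start + site_local else
        g$start + g$glen - 1L - site_local
      emit_read(iso$gene_id, iso, blocks_gen, g$strand, site_gen, tail_len,
                n_hits)
      k <- which(site_counts$gene_id == iso$gene_id &
                 site_counts$pos == sites$pos[si])
      site_counts$n_reads[k] <- site_counts$n_reads[k] + 1L
    }
  }

  for (ni in seq_len(nrow(sim$novel_loci))) {
    nl <- sim$novel_loci[ni, ]
    n_reads <- sample(params$reads_per_isoform[1]:params$reads_per_isoform[2],
                      1L)
    iso <- list(iso_id = paste0(nl$locus_id, ".1"), chrom = nl$chrom)
    for (r in seq_len(n_reads)) {
      blocks <- if (nl$strand == "+")
        matrix(c(nl$start, nl$polya_pos + 1L), 1L) else
        matrix(c(nl$polya_pos, nl$end), 1L)
      tail_len <- sample(params$tail_len[1]:params$tail_len[2], 1L)
      emit_read(nl$locus_id, iso, blocks, nl$strand, nl$polya_pos, tail_len,
                1L)
    }
  }

  list(reads = reads, alignments = alns, truth = do.call(rbind, truth),
       site_counts = site_counts)
}

genomic_to_local_exons <- function(ex_gen, g0, glen, strand) {
  loc <- t(apply(ex_gen, 1L, function(b) {
    if (strand == "+") c(b[1L] - g0, b[2L] - g0)
    else c(g0 + glen - b[2L], g0 + glen - b[1L])
  }))
  loc <- loc[order(loc[, 1L]), , drop = FALSE]
  storage.mode(loc) <- "integer"
  loc
}

truncate_5prime <- function(ex_local, trunc) {
  lens <- ex_local[, 2L] - ex_local[, 1L]
  cum <- cumsum(lens)
  keep_from <- which(cum > trunc)[1]
  removed_before <- if (keep_from > 1L) cum[keep_from - 1L] else 0L
  out <- ex_local[keep_from:nrow(ex_local), , drop = FALSE]
  out[1L, 1L] <- out[1L, 1L] + (trunc - removed_before)
  out
}

# inject mismatches and geometric-length indels into the genomic-orientation
# sequence of an exon-block chain, recording every edit in read coordinates
inject_errors <- function(genome, chrom, blocks, params) {
  p_mm <- params$mismatch_rate
  p_ins_ev <- params$insertion_rate / params$mean_ins_len
  p_del_ev <- params$deletion_rate / params$mean_del_len
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  edits <- list()
  for (b in seq_len(nrow(blocks))) {
    bs <- blocks[b, 1L]; be <- blocks[b, 2L]
    ref <- strsplit(seq_slice(genome, chrom, bs, be), "")[[1]]
    n <- length(ref)
    i <- 1L
    while (i <= n) {
      # deletions never touch block edges so the block chain stays intact
      if (i > 1L && i < n && runif(1) < p_del_ev) {
        dlen <- min(1L + rgeom(1L, 1 / params$mean_del_len), n - i)
        edits[[length(edits) + 1L]] <- list(kind = "deletion",
                                            ref_pos = bs + i - 1L,
                                            read_off = length(out),
                                            len = dlen)
        i <- i + dlen
        next
      }
      ch <- ref[i]
      if (runif(1) < p_mm) {
        ch <- sample(setdiff(bases, ref[i]), 1L)
        edits[[length(edits) + 1L]] <- list(kind = "mismatch",
                                            ref_pos = bs + i - 1L,
                                            read_off = length(out),
                                            len = 1L)
      }
      out[length(out) + 1L] <- ch
      if (i < n && runif(1) < p_ins_ev) {
        ilen <- 1L + rgeom(1L, 1 / params$mean_ins_len)
        ins <- sample(bases, ilen, replace = TRUE)
        edits[[length(edits) + 1L]] <- list(kind = "insertion",
                                            ref_pos = bs + i,
                                            read_off = length(out),
                                            len = ilen)
        out <- c(out, ins)
      }
      i <- i + 1L
    }
  }
  ed <- if (length(edits)) do.call(rbind, lapply(edits, as.data.frame)) else
    empty_edits()
  list(seq = paste(out, collapse = ""), edits = ed)
}

#' Write simulator outputs to disk
#'
#' Emits the genome FASTA, annotation GFF3, reads FASTA, true alignments as
#' SAM and truth tables as TSV.
#'
#' @param sim a `sim_truth`.
#' @param reads result of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_simulation <- function(sim, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gff3"),
    reads = file.path(dir, "reads.fa"),
    alignments = file.path(dir, "alignments.sam"),
    read_truth = file.path(dir, "read_truth.tsv"),
    polya_truth = file.path(dir, "polya_truth.tsv"),
    event_truth = file.path(dir, "event_truth.tsv"))
  write_genome_fasta(sim$genome, paths$genome)
  write_annotation_gff3(sim$annotation, paths$annotation)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads$reads),
                              paths$reads)
  write_sam(reads$alignments, sim$genome, paths$alignments)
  write.table(reads$truth, paths$read_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(reads$site_counts, paths$polya_truth, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$events, paths$event_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
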