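#' Detect a poly(A) cleavage site from a read alignment's soft clips
#'
#' A trailing soft clip of at least `min_tail` nucleotides whose A fraction
#' is at least `min_purity` calls a cleavage site at the last aligned
#' reference base on the `+` strand; a leading poly(T) clip symmetrically
#' calls a site at the first aligned base on `-`. The strict EST-style rule
#' (the clip consists *only* of A/T, clip length equal to the homopolymer
#' stretch) is available via `min_purity = 1`.
#'
#' @param aln a `read_aln`.
#' @param min_tail minimum clip length (default 5).
#' @param min_purity minimum A (or T) fraction (default 0.8).
#' @return data frame with one row (`chrom`, `pos`, `strand`, `read_id`) or
#'   `NULL` when no tail is found.
#' @export
detect_polya_tail <- function(aln, min_tail = 5L, min_purity = 0.8) {
  frac <- function(s, b) {
    n <- nchar(s)
    if (n == 0L) return(0)
    (n - nchar(gsub(b, "", s, fixed = TRUE))) / n
  }
  if (nchar(aln$clip3) >= min_tail && frac(aln$clip3, "A") >= min_purity)
    return(data.frame(chrom = aln$chrom, pos = aln_end(aln) - 1L,
                      strand = "+", read_id = aln$qname,
                      stringsAsFactors = FALSE))
  if (nchar(aln$clip5) >= min_tail && frac(aln$clip5, "T") >= min_purity)
    return(data.frame(chrom = aln$chrom, pos = aln_start(aln),
                      strand = "-", read_id = aln$qname,
                      stringsAsFactors = FALSE))
  NULL
}

#' Parameters for greedy poly(A)-site clustering
#'
#' @param window depth window half-width in nt: a read end `p` supports
#'   candidate `s` when `|p - s| <= window` (default 5).
#' @param min_depth minimum read depth for an accepted site (default 2).
#' @param min_spacing a candidate is rejected when it lies within this many
#'   nt of a previously accepted site (default 15).
#' @param merge_dist microheterogeneity merge distance in nt (default 15);
#'   retained for reporting, the greedy loop itself enforces `min_spacing`.
#' @return a `polya_params` list.
#' @export
polya_params <- function(window = 5L, min_depth = 2L, min_spacing = 15L,
                         merge_dist = 15L) {
  stopifnot(window >= 0L, min_depth >= 0L, min_spacing >= 0L, merge_dist >= 0L)
  structure(list(window = as.integer(window), min_depth = as.integer(min_depth),
                 min_spacing = as.integer(min_spacing),
                 merge_dist = as.integer(merge_dist)),
            class = "polya_params")
}

#' Greedy clustering of poly(A) read ends within one gene or locus
#'
#' The depth of each candidate site (each distinct read-end position) is the
#' number of read ends within `window` nt of it. The deepest candidate (ties
#' broken toward the smaller genomic coordinate) is accepted if its depth is
#' at least `min_depth` and it does not lie within `min_spacing` nt of a
#' previously accepted site; the candidate is then removed and the loop
#' continues until no candidates remain.
#'
#' @param read_ends integer vector of cleavage positions (one per read, same
#'   gene/locus and strand).
#' @param params a [polya_params()].
#' @return data frame of accepted clusters: `pos` (representative), `depth`,
#'   `members` (comma-separated member read-end positions within the
#'   window), ordered by decreasing depth (acceptance order).
#' @export
cluster_polya_sites <- function(read_ends, params = polya_params()) {
  out <- data.frame(pos = integer(0), depth = integer(0),
                    members = character(0), stringsAsFactors = FALSE)
  if (length(read_ends) == 0L) return(out)
  cand <- sort(unique(read_ends))
  accepted <- integer(0)
  while (length(cand)) {
    depth <- vapply(cand, function(s)
      sum(abs(read_ends - s) <= params$window), integer(1))
    best <- cand[depth == max(depth)][1]   # tie -> smaller coordinate
    bdepth <- max(depth)
    ok <- bdepth >= params$min_depth &&
      (!length(accepted) || all(abs(accepted - best) > params$min_spacing))
    if (ok) {
      accepted <- c(accepted, best)
      mem <- read_ends[abs(read_ends - best) <= params$window]
      out <- rbind(out, data.frame(pos = best, depth = bdepth,
                                   members = paste(sort(mem), collapse = ","),
                                   stringsAsFactors = FALSE))
    }
    cand <- cand[cand != best]
  }
  rownames(out) <- NULL
  out
}

#' Classify a poly(A) site's genic region
#'
#' Strand-aware comparison of the site position with the gene's START/STOP
#' codon coordinates: upstream of START is 5' UTR, downstream of STOP is
#' 3' UTR, between them is internal. When several START or STOP codons are
#' annotated, the pair minimizing the total UTR length (5' UTR + 3' UTR,
#' computed against the gene's transcript extent) is used before
#' classification (`per_site = FALSE`, the default, picks one pair per
#' gene; `per_site = TRUE` re-minimizes for each site).
#'
#' @param pos 0-based site position(s).
#' @param ann an `annotation_index`.
#' @param gene_id the gene the site(s) belong to.
#' @param per_site choose the codon pair per site instead of per gene.
#' @return character vector in `{utr5, internal, utr3, unclassified}`.
#' @export
classify_site <- function(pos, ann, gene_id, per_site = FALSE) {
  txs <- ann$transcripts[ann$transcripts$gene_id == gene_id, , drop = FALSE]
  if (nrow(txs) == 0L) return(rep("unclassified", length(pos)))
  strand <- txs$strand[1]
  starts <- ann$start_codons[ann$start_codons$tx_id %in% txs$tx_id, , drop = FALSE]
  stops <- ann$stop_codons[ann$stop_codons$tx_id %in% txs$tx_id, , drop = FALSE]
  if (nrow(starts) == 0L || nrow(stops) == 0L)
    return(rep("unclassified", length(pos)))
  tx_lo <- min(txs$start); tx_hi <- max(txs$end)
  # UTR-minimizing codon pair: 5' UTR smallest => START closest to the
  # transcript 5' end; 3' UTR smallest => STOP closest to the 3' end.
  if (strand == "+") {
    start_c <- min(starts$start); stop_c <- max(stops$end) - 1L
  } else {
    start_c <- max(starts$end) - 1L; stop_c <- min(stops$start)
  }
  classify_one <- function(p) {
    if (strand == "+") {
      if (p < start_c) "utr5" else if (p > stop_c) "utr3" else "internal"
    } else {
      if (p > start_c) "utr5" else if (p < stop_c) "utr3" else "internal"
    }
  }
  vapply(pos, classify_one, character(1))
}

#' Flag likely internal-priming artifacts
#'
#' True when the strand-aware genomic window immediately downstream of the
#' cleavage site contains at least `min_A` adenosines — evidence that the
#' oligo-dT primer may have annealed to genome-encoded A's rather than a
#' real tail. A window truncated by the chromosome end scales the threshold
#' proportionally.
#'
#' @param pos 0-based cleavage position.
#' @param chrom,strand site location.
#' @param genome `DNAStringSet`.
#' @param window downstream window size in nt (default 10).
#' @param min_A A count threshold (default 7).
#' @return logical.
#' @export
detect_internal_priming <- function(pos, chrom, strand, genome,
                                    window = 10L, min_A = 7L) {
  len <- Biostrings::width(genome[chrom])
  if (strand == "+") {
    lo <- pos + 1L; hi <- min(pos + window, len - 1L)
    if (lo > hi) return(FALSE)
    s <- seq_slice(genome, chrom, lo, hi + 1L)
  } else {
    hi <- pos - 1L; lo <- max(pos - window, 0L)
    if (lo > hi) return(FALSE)
    s <- revcomp(seq_slice(genome, chrom, lo, hi + 1L))
  }
  got <- nchar(s)
  thr <- if (got < window) ceiling(min_A * got / window) else min_A
  nA <- got - nchar(gsub("A", "", s, fixed = TRUE))
  nA >= thr
}

#' Per-gene alternative-polyadenylation summary
#'
#' A gene shows APA when it has two or more accepted poly(A) clusters; its
#' preferred site is the cluster holding a strict majority (> 50%) of the
#' gene's clustered poly(A) reads, if any.
#'
#' @param clusters_by_gene named list of cluster data frames (one per gene,
#'   as returned by [cluster_polya_sites()]).
#' @return data frame: `gene_id`, `n_sites`, `apa`, `preferred_pos` (NA when
#'   no site holds a majority), `preferred_frac`.
#' @export
call_apa <- function(clusters_by_gene) {
  rows <- lapply(names(clusters_by_gene), function(g) {
    cl <- clusters_by_gene[[g]]
    n <- nrow(cl)
    tot <- sum(cl$depth)
    pref <- NA_integer_; pfrac <- NA_real_
    if (n > 0L && tot > 0L) {
      fr <- cl$depth / tot
      if (max(fr) > 0.5) {
        k <- which.max(fr)
        pref <- cl$pos[k]; pfrac <- fr[k]
      }
    }
    data.frame(gene_id = g, n_sites = n, apa = n >= 2L,
               preferred_pos = pref, preferred_frac = pfrac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(gene_id = character(0), n_sites = integer(0),
               apa = logical(0), preferred_pos = integer(0),
               preferred_frac = numeric(0))
}

#' Nucleotide composition profile around cleavage sites
#'
#' Strand-oriented base frequencies at each position from `-flank` to
#' `+flank` relative to the cleavage site (position 0 is the cleavage site
#' itself, the last transcribed base). Sites closer than `flank` to a
#' chromosome edge are skipped and counted.
#'
#' @param sites data frame with `chrom`, `pos`, `strand`.
#' @param genome `DNAStringSet`.
#' @param flank flank size in nt (default 50).
#' @return a `nucleotide_profile`: list with `freq` (4 x (2*flank+1)
#'   matrix, rows A/C/G/T, frequencies over non-N bases summing to 1 per
#'   position), `n_sites`, `n_skipped`.
#' @export
nucleotide_profile <- function(sites, genome, flank = 50L) {
  stopifnot(nrow(sites) >= 1L)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4L, 2L * flank + 1L,
                   dimnames = list(bases, as.character(-flank:flank)))
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- site_flank_seq(sites$chrom[i], sites$pos[i], sites$strand[i],
                        genome, flank)
    if (is.null(s)) { skipped <- skipped + 1L; next }
    ch <- strsplit(s, "")[[1]]
    for (j in seq_along(ch))
      if (ch[j] %in% bases) counts[ch[j], j] <- counts[ch[j], j] + 1L
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(tot, 1L), "/")
  structure(list(freq = freq, n_sites = nrow(sites) - skipped,
                 n_skipped = skipped),
            class = "nucleotide_profile")
}

# strand-oriented window [-flank, +flank] around a cleavage site; NULL when
# the window runs off the chromosome
site_flank_seq <- function(chrom, pos, strand, genome, flank) {
  len <- Biostrings::width(genome[chrom])
  if (strand == "+") {
    lo <- pos - flank; hi <- pos + flank + 1L
    if (lo < 0L || hi > len) return(NULL)
    seq_slice(genome, chrom, lo, hi)
  } else {
    lo <- pos - flank; hi <- pos + flank + 1L
    if (lo < 0L || hi > len) return(NULL)
    revcomp(seq_slice(genome, chrom, lo, hi))
  }
}

#' Positional frequency of a motif around cleavage sites
#'
#' Counts exact motif matches starting at each strand-oriented offset in
#' `-flank .. flank - nchar(motif)` relative to the cleavage site (offset 0
#' = the cleavage position).
#'
#' @param sites data frame with `chrom`, `pos`, `strand`.
#' @param genome `DNAStringSet`.
#' @param motif nucleotide string, e.g. `"AATAAA"` (DNA alphabet).
#' @param flank flank size in nt (default 50).
#' @return data frame with `offset` and `count`.
#' @export
positional_motif_frequency <- function(sites, genome, motif = "AATAAA",
                                       flank = 50L) {
  m <- nchar(motif)
  stopifnot(m <= flank)
  offsets <- -flank:(flank - m)
  counts <- setNames(integer(length(offsets)), as.character(offsets))
  for (i in seq_len(nrow(sites))) {
    s <- site_flank_seq(sites$chrom[i], sites$pos[i], sites$strand[i],
                        genome, flank)
    if (is.null(s)) next
    hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in hits) {
      off <- h - 1L - flank
      if (off >= -flank && off <= flank - m)
        counts[as.character(off)] <- counts[as.character(off)] + 1L
    }
  }
  data.frame(offset = offsets, count = unname(counts))
}

#' Extract strand-oriented upstream sequences of poly(A) sites
#'
#' One record per cluster, suitable as input to an external motif finder;
#' edge-truncated sites are skipped with a warning.
#'
#' @param sites data frame with `chrom`, `pos`, `strand` and optionally
#'   `gene_id`.
#' @param genome `DNAStringSet`.
#' @param length upstream length in nt (default 50).
#' @param path optional FASTA output path.
#' @return named character vector of sequences (ids `gene:position:strand`);
#'   written to `path` when given.
#' @export
extract_upstream_sequences <- function(sites, genome, length = 50L,
                                       path = NULL) {
  stopifnot(length >= 1L)
  out <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]; pos <- sites$pos[i]; strand <- sites$strand[i]
    clen <- Biostrings::width(genome[chrom])
    s <- if (strand == "+") {
      if (pos - length < 0L) NULL else seq_slice(genome, chrom, pos - length, pos)
    } else {
      if (pos + 1L + length > clen) NULL
      else revcomp(seq_slice(genome, chrom, pos + 1L, pos + 1L + length))
    }
    if (is.null(s)) { skipped <- skipped + 1L; next }
    gid <- if (!is.null(sites$gene_id)) sites$gene_id[i] else chrom
    out[paste(gid, pos, strand, sep = ":")] <- s
  }
  if (skipped > 0L) warning(skipped, " edge-truncated site(s) skipped")
  if (!is.null(path))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out), path)
  out
}

#' Fraction of poly(A) sites in one set supported by another
#'
#' Restricted to genes present in both sets; a site in `sites_a` is
#' supported when some site in `sites_b` on the same gene and strand lies
#' within `tolerance` nt.
#'
#' @param sites_a,sites_b data frames with `gene_id`, `pos`, `strand`.
#' @param tolerance maximum distance in nt (default 15).
#' @return list with `fraction`, `n_supported`, `n_compared`.
#' @export
compare_polya_sets <- function(sites_a, sites_b, tolerance = 15L) {
  shared <- intersect(unique(sites_a$gene_id), unique(sites_b$gene_id))
  a <- sites_a[sites_a$gene_id %in% shared, , drop = FALSE]
  b <- sites_b[sites_b$gene_id %in% shared, , drop = FALSE]
  if (nrow(a) == 0L) return(list(fraction = NA_real_, n_supported = 0L,
                                 n_compared = 0L))
  supported <- vapply(seq_len(nrow(a)), function(i) {
    bb <- b[b$gene_id == a$gene_id[i] & b$strand == a$strand[i], , drop = FALSE]
    nrow(bb) > 0L && any(abs(bb$pos - a$pos[i]) <= tolerance)
  }, logical(1))
  list(fraction = mean(supported), n_supported = sum(supported),
       n_compared = nrow(a))
}

#' Write poly(A) clusters as BED6
#'
#' BED is 0-based half-open; each cluster becomes a single-base feature at
#' its representative position with `name = gene:class` and `score = depth`.
#'
#' @param clusters data frame with `chrom`, `pos`, `strand`, `depth` and
#'   optionally `gene_id`, `region`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polya_bed <- function(clusters, path) {
  name <- paste0(clusters$gene_id %||% clusters$chrom, ":",
                 clusters$region %||% "unclassified")
  bed <- data.frame(clusters$chrom, clusters$pos, clusters$pos + 1L, name,
                    clusters$depth, clusters$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
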