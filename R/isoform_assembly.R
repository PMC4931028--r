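#' Cluster stranded alignments into loci
#'
#' Clusters are the connected components of the same-strand genomic-overlap
#' graph (single linkage: two reads are linked when their aligned spans
#' overlap by at least one nucleotide; half-open abutting reads do not
#' overlap). Locus ids are assigned deterministically by
#' (chromosome, span start, strand).
#'
#' @param alignments list of `read_aln` with `tx_strand` assigned.
#' @return list of `read_cluster` objects: `locus_id`, `chrom`, `strand`,
#'   `span` (c(start, end)), `members` (list of `read_aln`).
#' @export
cluster_reads <- function(alignments) {
  if (length(alignments) == 0L) return(list())
  st <- vapply(alignments, function(a) a$tx_strand, character(1))
  if (any(st == "*")) stop("all alignments must have an assigned strand")
  gr <- GenomicRanges::GRanges(
    vapply(alignments, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(alignments, aln_start, integer(1)) + 1L,
                     vapply(alignments, aln_end, integer(1))),
    strand = st)
  comp <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  ord <- order(as.character(GenomicRanges::seqnames(comp)),
               GenomicRanges::start(comp),
               as.character(GenomicRanges::strand(comp)))
  comp <- comp[ord]
  lapply(seq_along(comp), function(i) {
    idx <- comp$revmap[[i]]
    members <- alignments[idx]
    structure(list(locus_id = paste0(pad_id("LOC", i),
                                     "_", as.character(
                                       GenomicRanges::seqnames(comp)[i])),
                   chrom = as.character(GenomicRanges::seqnames(comp)[i]),
                   strand = as.character(GenomicRanges::strand(comp)[i]),
                   span = c(GenomicRanges::start(comp)[i] - 1L,
                            GenomicRanges::end(comp)[i]),
                   members = members),
              class = "read_cluster")
  })
}

# is chain `b` a proper 3'-terminal sub-chain of `a`? (strand-aware; on "+"
# the 3' end is the rightmost introns, on "-" the leftmost)
is_3prime_suffix <- function(a, b, strand) {
  na <- nrow(a); nb <- nrow(b)
  if (nb == 0L || nb >= na) return(FALSE)
  sub <- if (strand == "+") a[(na - nb + 1L):na, , drop = FALSE]
         else a[1L:nb, , drop = FALSE]
  all(sub == b)
}

#' Collapse a read cluster into unique splice isoforms
#'
#' Reads with identical intron chains merge; a read whose intron chain is a
#' proper 3'-terminal suffix of another read's chain merges into that read's
#' isoform (transitively); reads that differ only in the downstream end of
#' their 3'-most exon never found distinct isoforms (identity is by intron
#' chain alone, so alternative polyadenylation does not split isoforms).
#' Unspliced reads merge into a spliced isoform when they lie within its
#' 3'-terminal exon region (downstream of its last intron, overlapping the
#' terminal exon); otherwise the cluster's remaining unspliced reads form
#' one intronless isoform.
#'
#' @param cluster a `read_cluster`.
#' @return list of `isoform` objects: `iso_id`, `chrom`, `strand`,
#'   `introns` (matrix), `read_ids`, `alns`, `intronless`.
#' @export
collapse_isoforms <- function(cluster) {
  members <- cluster$members
  strand <- cluster$strand
  if (length(members) == 0L) return(list())
  if (any(vapply(members, function(a) a$tx_strand, character(1)) != strand))
    stop("conflicting strands within cluster ", cluster$locus_id)
  chains <- lapply(members, aln_introns)
  keys <- vapply(chains, chain_key, character(1))
  spliced_i <- which(keys != "")
  iso_of <- integer(length(members))

  uk <- unique(keys[spliced_i])
  if (length(uk)) {
    uchain <- lapply(uk, function(k) chains[[spliced_i[match(k, keys[spliced_i])]]])
    parent <- seq_along(uk)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(uk)) for (j in seq_along(uk)) {
      if (i == j) next
      if (is_3prime_suffix(uchain[[i]], uchain[[j]], strand)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_along(uk), find, integer(1))
    comp_ids <- match(roots, sort(unique(roots)))
    iso_of[spliced_i] <- comp_ids[match(keys[spliced_i], uk)]
  }
  n_spliced_iso <- if (length(uk)) max(iso_of[spliced_i]) else 0L

  # per-isoform defining chain: member chain with the most introns
  # (ties broken by lexicographically smallest key)
  iso_chain <- vector("list", n_spliced_iso)
  for (g in seq_len(n_spliced_iso)) {
    cand <- which(iso_of == g)
    nn <- vapply(cand, function(i) nrow(chains[[i]]), integer(1))
    best <- cand[nn == max(nn)]
    best <- best[order(keys[best])][1]
    iso_chain[[g]] <- chains[[best]]
  }

  # unspliced reads: absorb into a spliced isoform's 3'-terminal exon region
  # (extents taken over the spliced members only, so the outcome does not
  # depend on the order unspliced reads are visited in)
  unspliced_i <- which(keys == "")
  leftover <- integer(0)
  if (length(unspliced_i)) {
    grp_ext <- lapply(seq_len(n_spliced_iso), function(g) {
      mem <- setdiff(which(iso_of == g), unspliced_i)
      c(min(vapply(members[mem], aln_start, integer(1))),
        max(vapply(members[mem], aln_end, integer(1))))
    })
    grp_size <- vapply(seq_len(n_spliced_iso), function(g)
      sum(iso_of == g), integer(1))
    for (i in unspliced_i) {
      a <- members[[i]]
      hit <- integer(0)
      for (g in seq_len(n_spliced_iso)) {
        ch <- iso_chain[[g]]
        inside <- if (strand == "+")
          aln_start(a) >= ch[nrow(ch), 2L] && aln_start(a) < grp_ext[[g]][2]
        else
          aln_end(a) <= ch[1L, 1L] && aln_end(a) > grp_ext[[g]][1]
        if (inside) hit <- c(hit, g)
      }
      if (length(hit)) {
        hit <- hit[grp_size[hit] == max(grp_size[hit])]
        hk <- vapply(hit, function(g) chain_key(iso_chain[[g]]), character(1))
        iso_of[i] <- hit[order(hk)][1]   # tie: smallest defining chain
      } else leftover <- c(leftover, i)
    }
    if (length(leftover)) {
      g <- n_spliced_iso + 1L
      iso_of[leftover] <- g
      iso_chain[[g]] <- introns_from_exons(matrix(integer(0), ncol = 2))
    }
  }

  groups <- unique(iso_of[iso_of > 0L])
  # deterministic, content-based isoform order: by defining chain, then by
  # the smallest member read id
  gkey <- vapply(groups, function(g)
    paste(chain_key(iso_chain[[g]]),
          min(vapply(members[iso_of == g], `[[`, character(1), "qname"))),
    character(1))
  groups <- groups[order(gkey)]
  isoforms <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    mem <- which(iso_of == g)
    structure(list(iso_id = paste0(cluster$locus_id, ".", gi),
                   locus_id = cluster$locus_id,
                   chrom = cluster$chrom, strand = strand,
                   introns = iso_chain[[g]],
                   read_ids = vapply(members[mem], `[[`, character(1), "qname"),
                   alns = members[mem],
                   intronless = nrow(iso_chain[[g]]) == 0L),
              class = "isoform")
  })
  isoforms
}

#' Build the representative transcript of an isoform
#'
#' The base read is the supporting read with the most aligned blocks (ties:
#' longest aligned span, then lexicographically smallest read id). Its first
#' exon is extended to the 5'-most coordinate over all supporting reads, and
#' its 3' end is set to the 3'-most supported poly(A) cleavage site among
#' the supporting reads (or the 3'-most alignment end when none has a site).
#'
#' @param iso an `isoform`.
#' @param polya_sites optional named integer vector mapping read id to
#'   cleavage position (0-based last transcribed base).
#' @return the isoform with `exons` (representative exon matrix) and
#'   `rep_read` fields set.
#' @export
build_representative <- function(iso, polya_sites = NULL) {
  alns <- iso$alns
  nb <- vapply(alns, function(a) nrow(a$blocks), integer(1))
  span <- vapply(alns, function(a) aln_end(a) - aln_start(a), integer(1))
  qn <- vapply(alns, `[[`, character(1), "qname")
  ord <- order(-nb, -span, qn)
  base <- alns[[ord[1]]]
  exons <- base$blocks
  starts <- vapply(alns, aln_start, integer(1))
  ends <- vapply(alns, aln_end, integer(1))
  sites <- if (!is.null(polya_sites))
    polya_sites[intersect(names(polya_sites), qn)] else integer(0)
  sites <- sites[!is.na(sites)]
  if (iso$strand == "+") {
    exons[1L, 1L] <- min(starts)
    end3 <- if (length(sites)) max(sites) + 1L else max(ends)
    exons[nrow(exons), 2L] <- max(end3, exons[nrow(exons), 1L] + 1L)
  } else {
    exons[nrow(exons), 2L] <- max(ends)
    end3 <- if (length(sites)) min(sites) else min(starts)
    exons[1L, 1L] <- min(end3, exons[1L, 2L] - 1L)
  }
  iso$exons <- exons
  iso$rep_read <- base$qname
  iso
}

#' Associate isoforms with annotated genes
#'
#' By default an isoform is associated with a gene when its representative
#' exons overlap the gene's annotated exons by at least one nucleotide on
#' the same strand (exonic mode); `mode = "genic"` relaxes this to overlap
#' with the gene's genomic extent. The association is the single gene id,
#' `character(0)` (novel candidate) or the vector of two or more gene ids
#' (read-through / misannotation candidates, excluded from splice-event
#' analysis downstream).
#'
#' @param isoforms list of `isoform` with `exons` set (see
#'   [build_representative()]).
#' @param ann an `annotation_index`.
#' @param mode `"exonic"` (default) or `"genic"`.
#' @return the isoforms, each with `gene_assoc` (character vector) set.
#' @export
associate_genes <- function(isoforms, ann, mode = c("exonic", "genic")) {
  mode <- match.arg(mode)
  target <- if (mode == "exonic") ann$exon_gr else ann$gene_gr
  lapply(isoforms, function(iso) {
    ex <- iso$exons
    q <- GenomicRanges::GRanges(iso$chrom,
                                IRanges::IRanges(ex[, 1L] + 1L, ex[, 2L]),
                                strand = iso$strand)
    hits <- GenomicRanges::findOverlaps(q, target, minoverlap = 1L)
    genes <- unique(target$gene_id[S4Vectors::subjectHits(hits)])
    iso$gene_assoc <- sort(genes)
    iso
  })
}

#' Flag full-length isoforms
#'
#' An isoform associated with a single gene is full-length when its 5'-most
#' exon starts within the genomic extent of the annotated first exon
#' (strand-aware) of any transcript of that gene.
#'
#' @param iso an `isoform` with a single-gene `gene_assoc` and `exons`.
#' @param ann an `annotation_index`.
#' @return logical.
#' @export
classify_full_length <- function(iso, ann) {
  if (length(iso$gene_assoc) != 1L)
    stop("full-length calling requires a single-gene association")
  txs <- ann$transcripts$tx_id[ann$transcripts$gene_id == iso$gene_assoc]
  p5 <- if (iso$strand == "+") iso$exons[1L, 1L] else
    iso$exons[nrow(iso$exons), 2L] - 1L
  for (tx in txs) {
    ex <- transcript_exons(ann, tx)
    fe <- if (iso$strand == "+") ex[1L, , drop = FALSE] else
      ex[nrow(ex), , drop = FALSE]
    if (p5 >= fe[1L, 1L] && p5 < fe[1L, 2L]) return(TRUE)
  }
  FALSE
}

#' Write isoforms as GTF
#'
#' Emits transcript + exon records with `supporting_read_count`, `novel`,
#' `full_length` and `gene_association` attributes.
#'
#' @param isoforms list of `isoform` objects with `exons` set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isoforms_gtf <- function(isoforms, path) {
  lines <- character(0)
  for (iso in isoforms) {
    gid <- if (length(iso$gene_assoc) == 1L) iso$gene_assoc else iso$locus_id
    attrs <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                            'supporting_read_count "%d"; novel "%s"; ',
                            'full_length "%s"; gene_association "%s";'),
                     gid, iso$iso_id, length(iso$read_ids),
                     tolower(as.character(isTRUE(iso$novel))),
                     tolower(as.character(isTRUE(iso$full_length))),
                     if (length(iso$gene_assoc)) paste(iso$gene_assoc,
                                                       collapse = ",")
                     else "none")
    span <- c(iso$exons[1L, 1L], iso$exons[nrow(iso$exons), 2L])
    lines <- c(lines, paste(iso$chrom, "isopipe", "transcript", span[1] + 1L,
                            span[2], ".", iso$strand, ".", attrs, sep = "\t"))
    for (k in seq_len(nrow(iso$exons)))
      lines <- c(lines, paste(iso$chrom, "isopipe", "exon",
                              iso$exons[k, 1L] + 1L, iso$exons[k, 2L], ".",
                              iso$strand, ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
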