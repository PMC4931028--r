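# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These are deliberately naive (repeated
# passes, all-pairs scans) and share no code with the implementations.

# --- greedy poly(A) clustering: literal transcription of the procedure ----
# Candidates are the distinct read-end positions. Repeatedly: compute each
# candidate's depth (read ends within `window`), take the deepest (smaller
# coordinate on ties); add it to the accepted list if depth >= min_depth and
# it is not within min_spacing of an accepted site; remove it from the
# candidate list; stop when no candidates remain.
oracle_greedy_polya <- function(read_ends, window = 5L, min_depth = 2L,
                                min_spacing = 15L) {
  candidates <- unique(read_ends)
  accepted <- data.frame(pos = integer(0), depth = integer(0))
  repeat {
    if (length(candidates) == 0L) break
    depths <- sapply(candidates, function(s) {
      d <- 0L
      for (p in read_ends) if (abs(p - s) <= window) d <- d + 1L
      d
    })
    top <- candidates[depths == max(depths)]
    site <- min(top)
    site_depth <- max(depths)
    within_prev <- FALSE
    for (a in accepted$pos) if (abs(a - site) <= min_spacing)
      within_prev <- TRUE
    if (site_depth >= min_depth && !within_prev)
      accepted <- rbind(accepted, data.frame(pos = site, depth = site_depth))
    candidates <- setdiff(candidates, site)
  }
  accepted
}

# --- isoform collapsing: repeated-pass closure of the merge rules ---------
# reads: list of list(id, chain = matrix(start,end), start, end)
# Returns a partition: list of sorted character vectors of read ids.
oracle_collapse <- function(reads, strand) {
  n <- length(reads)
  key <- sapply(reads, function(r)
    if (nrow(r$chain)) paste(r$chain[, 1], r$chain[, 2], sep = "-",
                             collapse = ";") else "")
  spliced <- which(key != "")
  label <- seq_len(n)
  suffix_of <- function(long, short) {
    nl <- nrow(long); ns <- nrow(short)
    if (ns == 0L || ns >= nl) return(FALSE)
    idx <- if (strand == "+") (nl - ns + 1L):nl else 1L:ns
    all(long[idx, , drop = FALSE] == short)
  }
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in spliced) for (j in spliced) {
      if (label[i] == label[j]) next
      merge <- key[i] == key[j] ||
        suffix_of(reads[[i]]$chain, reads[[j]]$chain) ||
        suffix_of(reads[[j]]$chain, reads[[i]]$chain)
      if (merge) {
        label[label == max(label[i], label[j])] <- min(label[i], label[j])
        changed <- TRUE
      }
    }
  }
  # unspliced reads: absorb into the spliced group (largest, then smallest
  # group label) whose 3'-terminal exon region contains the read start
  # (strand-aware); leftovers form one intronless group
  groups <- unique(label[spliced])
  grp_chain <- lapply(groups, function(g) {
    mem <- spliced[label[spliced] == g]
    nn <- sapply(mem, function(i) nrow(reads[[i]]$chain))
    best <- mem[nn == max(nn)]
    ks <- sapply(best, function(i) key[i])
    reads[[best[order(ks)][1]]]$chain
  })
  grp_ext <- lapply(groups, function(g) {
    mem <- spliced[label[spliced] == g]
    c(min(sapply(mem, function(i) reads[[i]]$start)),
      max(sapply(mem, function(i) reads[[i]]$end)))
  })
  grp_n <- sapply(groups, function(g) sum(label[spliced] == g))
  unspliced <- setdiff(seq_len(n), spliced)
  leftover <- integer(0)
  for (i in unspliced) {
    r <- reads[[i]]
    hits <- integer(0)
    for (k in seq_along(groups)) {
      ch <- grp_chain[[k]]
      ok <- if (strand == "+")
        r$start >= ch[nrow(ch), 2] && r$start < grp_ext[[k]][2]
      else r$end <= ch[1, 1] && r$end > grp_ext[[k]][1]
      if (ok) hits <- c(hits, k)
    }
    if (length(hits)) {
      hits <- hits[grp_n[hits] == max(grp_n[hits])]
      hk <- sapply(hits, function(k)
        paste(grp_chain[[k]][, 1], grp_chain[[k]][, 2], sep = "-",
              collapse = ";"))
      label[i] <- groups[hits[order(hk)][1]]
    } else leftover <- c(leftover, i)
  }
  if (length(leftover)) label[leftover] <- n + 1L
  parts <- lapply(split(seq_len(n), label), function(ix)
    sort(sapply(ix, function(i) reads[[i]]$id)))
  unname(parts[order(sapply(parts, `[`, 1))])
}

# --- AS events: exhaustive pairwise path comparison -----------------------
# exon_sets: named list of exon matrices sharing a strand.
oracle_events <- function(exon_sets, strand) {
  introns_of <- function(ex) {
    if (nrow(ex) < 2L) return(matrix(integer(0), ncol = 2L))
    cbind(ex[-nrow(ex), 2L], ex[-1L, 1L])
  }
  found <- character(0)
  add <- function(type, c1, c2, shared = "")
    found <<- c(found, paste(type, c1, c2, shared))
  ids <- seq_along(exon_sets)
  for (a in ids) for (b in ids) {
    if (a == b) next
    exA <- exon_sets[[a]]; exB <- exon_sets[[b]]
    inA <- introns_of(exA); inB <- introns_of(exB)
    for (i in seq_len(nrow(inA))) for (e in seq_len(nrow(exB)))
      if (exB[e, 1] <= inA[i, 1] && inA[i, 2] <= exB[e, 2])
        add("intron_retention", inA[i, 1], inA[i, 2])
    for (e in seq_len(nrow(exA))) {
      present_in_B <- any(exB[, 1] == exA[e, 1] & exB[, 2] == exA[e, 2])
      if (present_in_B) next
      for (i in seq_len(nrow(inB)))
        if (inB[i, 1] <= exA[e, 1] && exA[e, 2] <= inB[i, 2])
          add("exon_skipping", exA[e, 1], exA[e, 2])
    }
    for (i in seq_len(nrow(inA))) for (j in seq_len(nrow(inB))) {
      i1 <- inA[i, ]; i2 <- inB[j, ]
      if (all(i1 == i2)) next
      overl <- function(x, y) x[1] < y[2] && y[1] < x[2]
      if (i1[1] == i2[1] && i1[2] != i2[2]) {
        rA <- exA[i + 1L, ]; rB <- exB[j + 1L, ]
        if (overl(rA, rB)) {
          type <- if (strand == "+") "alt_3prime" else "alt_5prime"
          add(type, min(i1[2], i2[2]), max(i1[2], i2[2]), i1[1])
        }
      }
      if (i1[2] == i2[2] && i1[1] != i2[1]) {
        lA <- exA[i, ]; lB <- exB[j, ]
        if (overl(lA, lB)) {
          type <- if (strand == "+") "alt_5prime" else "alt_3prime"
          add(type, min(i1[1], i2[1]), max(i1[1], i2[1]), i1[2])
        }
      }
    }
  }
  sort(unique(found))
}

event_set_of <- function(ev)
  sort(unique(paste(ev$type, ev$coord1, ev$coord2,
                    ifelse(is.na(ev$shared), "", ev$shared))))

# --- longest ORF: regex-based scan ----------------------------------------
oracle_orf <- function(seq) {
  best <- 0L
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(0L)
  n <- nchar(seq)
  for (s in starts) {
    i <- s + 3L
    while (i + 2L <= n) {
      cod <- substr(seq, i, i + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, i - s)
        break
      }
      i <- i + 3L
    }
  }
  best
}

# --- random alignment-record factory for collapse tests -------------------
# Builds a synthetic cluster of reads on a shared exon scaffold; returns a
# read_cluster plus the plain-list view the oracle consumes.
random_cluster <- function(n_reads, strand = "+", seed_exons = 4L) {
  bnd <- sort(sample(seq(100L, 4000L, by = 50L), 2L * seed_exons))
  scaffold <- matrix(bnd, ncol = 2L, byrow = TRUE)
  alns <- list(); oreads <- list()
  for (r in seq_len(n_reads)) {
    if (runif(1) < 0.2) {   # unspliced read somewhere on the scaffold
      e <- scaffold[sample.int(seed_exons, 1L), ]
      s <- sort(sample(e[1]:(e[2] - 1L), 2L))
      blocks <- matrix(c(s[1], s[2] + 1L), 1L)
    } else {
      k <- sample.int(seed_exons - 1L, 1L)     # 5' truncation point
      blocks <- scaffold[k:seed_exons, , drop = FALSE]
      if (runif(1) < 0.3)                      # APA-style 3' end variation
        blocks[nrow(blocks), 2L] <- blocks[nrow(blocks), 2L] -
          sample(0:40, 1L)
      if (runif(1) < 0.3)                      # shifted terminal boundary
        blocks[1L, 1L] <- blocks[1L, 1L] + sample(0:30, 1L)
    }
    id <- sprintf("r%03d", r)
    seqlen <- sum(blocks[, 2L] - blocks[, 1L])
    alns[[r]] <- read_aln(id, "chrS", strand, blocks,
                          strrep("A", seqlen), tx_strand = strand)
    ic <- if (nrow(blocks) > 1L)
      cbind(blocks[-nrow(blocks), 2L], blocks[-1L, 1L])
    else matrix(integer(0), ncol = 2L)
    oreads[[r]] <- list(id = id, chain = ic, start = blocks[1L, 1L],
                        end = blocks[nrow(blocks), 2L])
  }
  cluster <- structure(list(locus_id = "LOCTEST", chrom = "chrS",
                            strand = strand,
                            span = c(min(sapply(oreads, `[[`, "start")),
                                     max(sapply(oreads, `[[`, "end"))),
                            members = alns),
                       class = "read_cluster")
  list(cluster = cluster, oreads = oreads)
}

partition_of_isoforms <- function(isoforms)
  unname(lapply(isoforms, function(i) sort(i$read_ids))[
    order(sapply(lapply(isoforms, function(i) sort(i$read_ids)), `[`, 1))])

# small deterministic simulated data set shared across tests
small_sim <- function(seed = 42L, n_genes = 20L, ...) {
  p <- sim_params(seed = seed, n_genes = n_genes, ...)
  sim <- simulate_genome(p)
  reads <- simulate_reads(sim)
  list(params = p, sim = sim, reads = reads)
}
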