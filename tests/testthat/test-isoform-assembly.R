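mk_aln <- function(id, blocks, strand = "+", chrom = "chr1") {
  b <- matrix(as.integer(blocks), ncol = 2, byrow = TRUE)
  read_aln(id, chrom, strand, b, strrep("A", sum(b[, 2] - b[, 1])),
           tx_strand = strand)
}

test_that("read clustering is single-linkage with half-open boundary semantics", {
  a <- mk_aln("a", c(0, 100)); b <- mk_aln("b", c(50, 150))
  c_ <- mk_aln("c", c(100, 200))
  cl <- cluster_reads(list(a, b))
  expect_length(cl, 1L)
  cl2 <- cluster_reads(list(a, c_))   # abutting, zero overlap
  expect_length(cl2, 2L)
  # chain A-B, B-C where A and C do not overlap: one component
  x <- mk_aln("x", c(0, 100)); y <- mk_aln("y", c(80, 220))
  z <- mk_aln("z", c(200, 300))
  expect_length(cluster_reads(list(x, y, z)), 1L)
  # opposite strands never cluster together
  w <- mk_aln("w", c(0, 100), strand = "-")
  expect_length(cluster_reads(list(a, w)), 2L)
})

test_that("identical chains merge; 3' suffixes merge; 5' prefixes do not", {
  A1 <- mk_aln("A1", c(50, 100, 200, 300, 400, 500))
  A2 <- mk_aln("A2", c(60, 100, 200, 300, 400, 480))
  C <- mk_aln("C", c(250, 300, 400, 500))       # chain = 3' suffix of A
  D <- mk_aln("D", c(50, 100, 200, 320))        # chain = 5' prefix of A
  cl <- cluster_reads(list(A1, A2, C, D))[[1]]
  isos <- collapse_isoforms(cl)
  parts <- lapply(isos, function(i) sort(i$read_ids))
  expect_length(isos, 2L)
  expect_true(list(c("A1", "A2", "C")) %in% parts ||
              any(vapply(parts, identical, logical(1), c("A1", "A2", "C"))))
  expect_true(any(vapply(parts, identical, logical(1), "D")))
})

test_that("3'-suffix merging is strand-aware", {
  # on the minus strand the 3' end is the genomic left
  A <- mk_aln("A", c(50, 100, 200, 300, 400, 500), strand = "-")
  S <- mk_aln("S", c(60, 100, 200, 260), strand = "-")  # leftmost introns
  cl <- cluster_reads(list(A, S))[[1]]
  expect_length(collapse_isoforms(cl), 1L)
  # the genomic-right suffix does NOT merge on minus
  R <- mk_aln("R", c(250, 300, 400, 500), strand = "-")
  cl2 <- cluster_reads(list(A, R))[[1]]
  expect_length(collapse_isoforms(cl2), 2L)
})

test_that("APA-style 3'-end differences never split isoforms", {
  r1 <- mk_aln("r1", c(0, 100, 200, 900))
  r2 <- mk_aln("r2", c(0, 100, 200, 950))
  isos <- collapse_isoforms(cluster_reads(list(r1, r2))[[1]])
  expect_length(isos, 1L)
  expect_setequal(isos[[1]]$read_ids, c("r1", "r2"))
})

test_that("unspliced reads join a spliced isoform only via its 3'-terminal exon", {
  sp <- mk_aln("sp", c(0, 100, 200, 600))
  term <- mk_aln("term", c(250, 500))     # inside terminal exon
  mid <- mk_aln("mid", c(20, 80))         # inside first exon
  isos <- collapse_isoforms(cluster_reads(list(sp, term, mid))[[1]])
  expect_length(isos, 2L)
  spliced <- Filter(function(i) !i$intronless, isos)[[1]]
  expect_setequal(spliced$read_ids, c("sp", "term"))
  intronless <- Filter(function(i) i$intronless, isos)[[1]]
  expect_equal(intronless$read_ids, "mid")
})

test_that("collapsing is order-independent", {
  set.seed(31)
  for (k in 1:20) {
    rc <- random_cluster(sample(3:8, 1), strand = sample(c("+", "-"), 1))
    base <- partition_of_isoforms(collapse_isoforms(rc$cluster))
    perm <- rc$cluster
    perm$members <- perm$members[sample(length(perm$members))]
    shuffled <- partition_of_isoforms(collapse_isoforms(perm))
    expect_equal(lapply(base, paste, collapse = ","),
                 lapply(shuffled, paste, collapse = ","))
  }
})

test_that("collapsing agrees with the brute-force closure of the merge rules", {
  set.seed(77)
  n_mismatch <- 0
  for (k in 1:150) {
    strand <- sample(c("+", "-"), 1)
    rc <- random_cluster(sample(2:8, 1), strand = strand)
    got <- partition_of_isoforms(collapse_isoforms(rc$cluster))
    want <- oracle_collapse(rc$oreads, strand)
    if (!identical(sapply(got, paste, collapse = ","),
                   sapply(want, paste, collapse = ",")))
      n_mismatch <- n_mismatch + 1
  }
  expect_equal(n_mismatch, 0)
})

test_that("every stranded filtered read supports exactly one isoform", {
  s <- small_sim(seed = 3, mismatch_rate = 0, insertion_rate = 0,
                 deletion_rate = 0)
  clusters <- cluster_reads(lapply(s$reads$alignments, function(a) {
    a$tx_strand <- a$strand
    a
  }))
  isos <- unlist(lapply(clusters, collapse_isoforms), recursive = FALSE)
  supporting <- unlist(lapply(isos, `[[`, "read_ids"))
  expect_equal(sort(supporting), sort(names(s$reads$reads)))
  expect_false(anyDuplicated(supporting) > 0)
})

test_that("representative transcript: base read choice, 5' extension, 3' poly(A)", {
  single <- mk_aln("s", c(100, 200, 300, 400))
  iso1 <- collapse_isoforms(cluster_reads(list(single))[[1]])[[1]]
  rep1 <- build_representative(iso1)
  expect_equal(unname(rep1$exons), unname(single$blocks))

  base <- mk_aln("b", c(100, 200, 300, 400, 500, 620))
  other <- mk_aln("o", c(80, 200, 300, 400, 500, 600))
  iso <- collapse_isoforms(cluster_reads(list(base, other))[[1]])[[1]]
  rep <- build_representative(iso, polya_sites = c(b = 950L, o = 989L))
  expect_equal(unname(rep$exons[1, 1]), 80L)      # 5'-most start over supports
  expect_equal(unname(rep$exons[nrow(rep$exons), 2]), 990L)  # 3'-most site + 1
  # without poly(A) evidence: 3'-most alignment end
  rep2 <- build_representative(iso)
  expect_equal(unname(rep2$exons[nrow(rep2$exons), 2]), 620L)
})

test_that("gene association requires exonic overlap on the same strand", {
  s <- small_sim(seed = 9, n_genes = 5L, mismatch_rate = 0,
                 insertion_rate = 0, deletion_rate = 0,
                 as_events = c(intron_retention = 1L, exon_skipping = 0L,
                               alt_5prime = 0L, alt_3prime = 0L))
  ann <- s$sim$annotation
  g1 <- ann$genes[1, ]
  tx <- ann$transcripts$tx_id[ann$transcripts$gene_id == g1$gene_id][1]
  ex <- transcript_exons(ann, tx)
  mk_iso <- function(id, exons, strand) {
    structure(list(iso_id = id, locus_id = id, chrom = g1$chrom,
                   strand = strand, introns = introns_from_chain(exons),
                   read_ids = "r", exons = exons, intronless = FALSE),
              class = "isoform")
  }
  introns_from_chain <- function(e)
    if (nrow(e) < 2) matrix(integer(0), ncol = 2) else
      cbind(e[-nrow(e), 2], e[-1, 1])
  inside <- mk_iso("i1", ex[1, , drop = FALSE] + c(5L, -5L), g1$strand)
  intronic <- if (nrow(ex) > 1)
    mk_iso("i2", matrix(c(ex[1, 2] + 5L, ex[2, 1] - 5L), 1), g1$strand)
  anti <- mk_iso("i3", ex[1, , drop = FALSE],
                 if (g1$strand == "+") "-" else "+")
  out <- associate_genes(list(inside, intronic, anti), ann)
  expect_equal(out[[1]]$gene_assoc, g1$gene_id)
  expect_length(out[[2]]$gene_assoc, 0L)   # intron-only overlap: none
  expect_length(out[[3]]$gene_assoc, 0L)   # antisense: none
  # genic mode absorbs the intronic isoform
  out2 <- associate_genes(list(intronic), ann, mode = "genic")
  expect_equal(out2[[1]]$gene_assoc, g1$gene_id)
})

test_that("full-length calling is strand-aware", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t1000\t.\t+\t.\tID=gp",
    "chr1\tx\tmRNA\t101\t1000\t.\t+\t.\tID=tp;Parent=gp",
    "chr1\tx\texon\t101\t250\t.\t+\t.\tParent=tp",
    "chr1\tx\texon\t301\t1000\t.\t+\t.\tParent=tp",
    "chr2\tx\tgene\t101\t1000\t.\t-\t.\tID=gm",
    "chr2\tx\tmRNA\t101\t1000\t.\t-\t.\tID=tm;Parent=gm",
    "chr2\tx\texon\t101\t800\t.\t-\t.\tParent=tm",
    "chr2\tx\texon\t901\t1000\t.\t-\t.\tParent=tm"), gff)
  ann <- load_annotation(gff)
  iso <- function(chrom, strand, exons, assoc)
    structure(list(iso_id = "q", chrom = chrom, strand = strand,
                   exons = matrix(as.integer(exons), ncol = 2, byrow = TRUE),
                   gene_assoc = assoc), class = "isoform")
  # + strand: 5' start inside annotated first exon [100,250)
  expect_true(classify_full_length(iso("chr1", "+", c(180, 600), "gp"), ann))
  expect_false(classify_full_length(iso("chr1", "+", c(260, 600), "gp"), ann))
  # - strand: first exon is the genomic-rightmost [900,1000)
  expect_true(classify_full_length(iso("chr2", "-", c(200, 950), "gm"), ann))
  expect_false(classify_full_length(iso("chr2", "-", c(200, 850), "gm"), ann))
  expect_error(classify_full_length(iso("chr1", "+", c(0, 10),
                                        character(0)), ann))
})
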