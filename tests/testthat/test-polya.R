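test_that("poly(A) tails are detected from soft clips with a purity gate", {
  plus <- read_aln("p", "chr1", "+", matrix(c(500L, 1000L), 1),
                   strrep("C", 500), clip3 = strrep("A", 10))
  s <- detect_polya_tail(plus)
  expect_equal(s$pos, 999L)
  expect_equal(s$strand, "+")
  minus <- read_aln("m", "chr1", "-", matrix(c(500L, 1000L), 1),
                    strrep("C", 500), clip5 = strrep("T", 10))
  s2 <- detect_polya_tail(minus)
  expect_equal(s2$pos, 500L)
  expect_equal(s2$strand, "-")
  impure <- read_aln("i", "chr1", "+", matrix(c(500L, 1000L), 1),
                     strrep("C", 500), clip3 = "ACGTACGTAC")
  expect_null(detect_polya_tail(impure))
  short <- read_aln("s", "chr1", "+", matrix(c(500L, 1000L), 1),
                    strrep("C", 500), clip3 = "AAA")
  expect_null(detect_polya_tail(short))
})

test_that("greedy clustering reproduces hand-traced examples", {
  r <- cluster_polya_sites(c(100, 100, 101, 120, 121, 400))
  expect_equal(r$pos, c(100L, 120L))
  expect_equal(r$depth, c(3L, 2L))
  r2 <- cluster_polya_sites(c(100, 101))
  expect_equal(r2$pos, 100L)      # tie broken toward smaller coordinate
  expect_equal(r2$depth, 2L)
  expect_equal(nrow(cluster_polya_sites(c(100))), 0L)  # min-depth gate
  expect_equal(nrow(cluster_polya_sites(integer(0))), 0L)
})

test_that("greedy clustering matches the brute-force loop on random inputs", {
  set.seed(2024)
  for (k in 1:400) {
    n <- sample(1:12, 1)
    ends <- sample(0:80, n, replace = TRUE)
    got <- cluster_polya_sites(ends)
    want <- oracle_greedy_polya(ends)
    expect_equal(got$pos, want$pos, info = paste(ends, collapse = ","))
    expect_equal(got$depth, want$depth)
  }
})

test_that("accepted clusters respect spacing and conserve read ends", {
  set.seed(8)
  for (k in 1:40) {
    ends <- sample(0:200, sample(5:40, 1), replace = TRUE)
    cl <- cluster_polya_sites(ends)
    if (nrow(cl) > 1)
      expect_true(all(abs(diff(sort(cl$pos))) > 15))
    expect_lte(sum(cl$depth), length(ends))
    for (i in seq_len(nrow(cl))) {
      mem <- as.integer(strsplit(cl$members[i], ",")[[1]])
      expect_true(all(abs(mem - cl$pos[i]) <= 5))
    }
  }
})

test_that("two well-separated planted sites are recovered exactly", {
  ends <- c(100, 100, 102, 98, 131, 131, 133)   # 31 nt apart, 4 + 3 reads
  cl <- cluster_polya_sites(ends)
  expect_equal(nrow(cl), 2L)
  expect_true(all(abs(sort(cl$pos) - c(100, 131)) <= 2))
})

test_that("site classification uses UTR-minimizing codon pairs", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t900\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t900\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tx\texon\t1\t900\t.\t+\t.\tParent=t1",
    "chr1\tx\tstart_codon\t201\t203\t.\t+\t.\tParent=t1",
    "chr1\tx\tstop_codon\t751\t753\t.\t+\t.\tParent=t1",
    "chr1\tx\tstop_codon\t801\t803\t.\t+\t.\tParent=t1"), gff)
  ann <- load_annotation(gff)
  # multiple stops: 800 (0-based) minimizes the 3' UTR, so 770 is internal
  expect_equal(classify_site(c(900, 770, 150, 500), ann, "g1"),
               c("utr3", "internal", "utr5", "internal"))
})

test_that("site classification is strand-aware and handles missing codons", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t900\t.\t-\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t900\t.\t-\t.\tID=t1;Parent=g1",
    "chr1\tx\texon\t1\t900\t.\t-\t.\tParent=t1",
    "chr1\tx\tstart_codon\t701\t703\t.\t-\t.\tParent=t1",
    "chr1\tx\tstop_codon\t201\t203\t.\t-\t.\tParent=t1",
    "chr1\tx\tgene\t1000\t1100\t.\t+\t.\tID=g2",
    "chr1\tx\tmRNA\t1000\t1100\t.\t+\t.\tID=t2;Parent=g2",
    "chr1\tx\texon\t1000\t1100\t.\t+\t.\tParent=t2"), gff)
  ann <- load_annotation(gff)
  expect_equal(classify_site(c(800, 400, 100), ann, "g1"),
               c("utr5", "internal", "utr3"))
  expect_equal(classify_site(1050, ann, "g2"), "unclassified")
})

test_that("internal priming flags genome-encoded downstream A stretches", {
  g <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("C", 100), "AAAAAAAAAA", strrep("C", 100),
                  "AAAAAAAGCT", strrep("C", 100))))
  expect_true(detect_internal_priming(99L, "chr1", "+", g))
  expect_true(detect_internal_priming(209L, "chr1", "+", g))  # exactly 7 A
  expect_false(detect_internal_priming(150L, "chr1", "+", g))
  # minus strand: downstream means genomic left, T-stretch complements to A
  g2 <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("C", 50), strrep("T", 10), strrep("G", 50))))
  expect_true(detect_internal_priming(60L, "chr1", "-", g2))
  expect_false(detect_internal_priming(30L, "chr1", "-", g2))
})

test_that("APA calling applies the strict-majority preferred-site rule", {
  mk <- function(depths) data.frame(pos = seq(100, by = 50,
                                              length.out = length(depths)),
                                    depth = depths,
                                    members = "x")
  apa <- call_apa(list(g1 = mk(5), g2 = mk(c(6, 3)), g3 = mk(c(3, 3))))
  expect_equal(apa$apa, c(FALSE, TRUE, TRUE))
  expect_equal(apa$preferred_pos, c(100L, 100L, NA_integer_))
  expect_equal(apa$preferred_frac[2], 6 / 9)
  expect_true(is.na(apa$preferred_frac[3]))   # exactly 50% is not preferred
})

test_that("nucleotide profile is strand-oriented with unit column sums", {
  core <- paste(rep(c("A", "C", "G", "T"), length.out = 101), collapse = "")
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("G", 50), core,
                                                strrep("G", 50))))
  sites <- data.frame(chrom = "chr1", pos = 100L, strand = "+")
  prof <- nucleotide_profile(sites, g, flank = 50L)
  expect_equal(dim(prof$freq), c(4L, 101L))
  expect_true(all(abs(colSums(prof$freq) - 1) < 1e-9))
  expect_equal(prof$freq["G", "0"], 1)   # site base is G by construction
  # complementary flanks on opposite strands give identical profiles
  sites2 <- data.frame(chrom = "chr1", pos = 100L, strand = "-")
  g2 <- Biostrings::DNAStringSet(c(chr1 = as.character(
    Biostrings::reverseComplement(g[[1]]))))
  prof2 <- nucleotide_profile(
    data.frame(chrom = "chr1",
               pos = Biostrings::width(g2[1]) - 1L - 100L,
               strand = "-"), g2, flank = 50L)
  expect_equal(prof2$freq, prof$freq)
  # edge sites are skipped and counted
  prof3 <- nucleotide_profile(rbind(sites,
                                    data.frame(chrom = "chr1", pos = 10L,
                                               strand = "+")), g, 50L)
  expect_equal(prof3$n_skipped, 1L)
})

test_that("the planted poly(A) signal peaks at its planted offset", {
  s <- small_sim(seed = 42)
  mf <- positional_motif_frequency(s$sim$polya_sites, s$sim$genome,
                                   "AATAAA", 50L)
  expect_equal(mf$offset[which.max(mf$count)], -25L)
  expect_gte(max(mf$count), 0.6 * nrow(s$sim$polya_sites))
  # absent motif: all-zero counts
  mf0 <- positional_motif_frequency(s$sim$polya_sites[1, , drop = FALSE],
                                    s$sim$genome, "AAAAAAAAAAAA", 50L)
  expect_true(all(mf0$count[mf0$offset < -20] == 0))
})

test_that("upstream sequence extraction is strand-oriented with unique ids", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), 500), collapse = "")))
  sites <- data.frame(chrom = "chr1", pos = c(1000L, 1000L, 1200L),
                      strand = c("+", "-", "+"),
                      gene_id = c("g1", "g2", "g3"))
  out <- extract_upstream_sequences(sites, g, length = 50L)
  expect_length(out, 3L)
  expect_false(anyDuplicated(names(out)) > 0)
  expect_equal(unname(out[1]),
               extract_sequence(g, genomic_interval("chr1", 950, 1000, "+")))
  expect_equal(unname(out[2]),
               extract_sequence(g, genomic_interval("chr1", 1001, 1051, "-")))
})

test_that("poly(A) set comparison restricts to shared genes and applies tolerance", {
  a <- data.frame(gene_id = c("g1", "g1", "g2"), pos = c(100L, 300L, 50L),
                  strand = "+")
  b <- data.frame(gene_id = c("g1", "g3"), pos = c(114L, 50L), strand = "+")
  r <- compare_polya_sets(a, b, tolerance = 15L)
  expect_equal(r$n_compared, 2L)      # g2 is not shared
  expect_equal(r$n_supported, 1L)     # |114-100| <= 15; 300 unsupported
  b2 <- data.frame(gene_id = "g1", pos = 116L, strand = "+")
  expect_equal(compare_polya_sets(a, b2)$n_supported, 0L)
  expect_equal(compare_polya_sets(a, a)$fraction, 1)
})
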