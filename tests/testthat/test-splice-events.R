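ex <- function(...) matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)

graph_of <- function(exon_sets, strand = "+")
  build_splice_graph(exon_sets, chrom = "chr1", strand = strand)

test_that("splice graph has deduplicated nodes and observed edges", {
  g1 <- graph_of(list(a = ex(0, 100, 200, 300)))
  expect_equal(nrow(g1$nodes), 2L)
  expect_equal(nrow(g1$edges), 1L)
  g2 <- graph_of(list(a = ex(0, 100, 200, 300, 400, 500),
                      b = ex(0, 100, 400, 500)))
  expect_equal(nrow(g2$nodes), 3L)
  expect_equal(nrow(g2$edges), 3L)   # E1-E2, E2-E3, E1-E3
  expect_error(build_splice_graph(list(
    structure(list(iso_id = "x", chrom = "c", strand = "+",
                   exons = ex(0, 10)), class = "isoform"),
    structure(list(iso_id = "y", chrom = "c", strand = "-",
                   exons = ex(0, 10)), class = "isoform"))), "mixed strands")
})

test_that("intron retention and exon skipping match their definitions", {
  ir <- classify_events(graph_of(list(a = ex(0, 100, 200, 300),
                                      b = ex(0, 300))))
  expect_equal(ir$type, "intron_retention")
  expect_equal(c(ir$coord1, ir$coord2), c(100L, 200L))

  es <- classify_events(graph_of(list(a = ex(0, 100, 200, 300, 400, 500),
                                      b = ex(0, 100, 400, 500))))
  expect_equal(es$type, "exon_skipping")
  expect_equal(c(es$coord1, es$coord2), c(200L, 300L))
  # a skipping bridge must not double as an alt-donor/acceptor event
  expect_equal(nrow(es), 1L)
})

test_that("alternative donor/acceptor naming is strand-aware", {
  sets <- list(a = ex(0, 100, 200, 300), b = ex(0, 120, 200, 300))
  plus <- classify_events(graph_of(sets, "+"))
  expect_equal(plus$type, "alt_5prime")
  expect_equal(c(plus$coord1, plus$coord2, plus$shared), c(100L, 120L, 200L))
  minus <- classify_events(graph_of(sets, "-"))
  expect_equal(minus$type, "alt_3prime")

  sets3 <- list(a = ex(0, 100, 200, 300), b = ex(0, 100, 220, 300))
  expect_equal(classify_events(graph_of(sets3, "+"))$type, "alt_3prime")
  expect_equal(classify_events(graph_of(sets3, "-"))$type, "alt_5prime")
})

test_that("event classification is symmetric in isoform order", {
  sets <- list(a = ex(0, 100, 200, 300, 400, 500),
               b = ex(0, 100, 150, 500),
               c = ex(0, 100, 400, 500))
  e1 <- event_set_of(classify_events(graph_of(sets)))
  e2 <- event_set_of(classify_events(graph_of(rev(sets))))
  expect_equal(e1, e2)
})

test_that("classification agrees with exhaustive pairwise-path comparison", {
  set.seed(123)
  mismatches <- 0
  for (k in 1:120) {
    strand <- sample(c("+", "-"), 1)
    n_iso <- sample(2:5, 1)
    bounds <- sort(sample(seq(0, 2000, by = 20), 12))
    scaffold <- matrix(bounds[1:12], ncol = 2, byrow = TRUE)
    sets <- lapply(seq_len(n_iso), function(i) {
      keep <- sort(sample(1:6, sample(2:6, 1)))
      m <- scaffold[keep, , drop = FALSE]
      if (runif(1) < 0.4 && nrow(m) > 1) {  # merge two adjacent exons (IR)
        j <- sample(nrow(m) - 1, 1)
        m[j, 2] <- m[j + 1, 2]
        m <- m[-(j + 1), , drop = FALSE]
      }
      if (runif(1) < 0.4 && nrow(m) > 1) {  # shift an internal boundary
        j <- sample(nrow(m) - 1, 1)
        m[j, 2] <- m[j, 2] - sample(c(4L, 8L), 1)
      }
      m
    })
    names(sets) <- paste0("i", seq_len(n_iso))
    got <- event_set_of(classify_events(graph_of(sets, strand)))
    want <- oracle_events(sets, strand)
    if (!identical(got, want)) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("events planted by the simulator are classified exactly", {
  s <- small_sim(seed = 42, n_novel_loci = 0L)
  sim <- s$sim
  found <- list()
  for (g in unique(sim$genes$gene_id)) {
    isos <- Filter(function(i) i$gene_id == g, sim$isoforms)
    if (length(isos) < 2L) next
    sets <- lapply(isos, `[[`, "exons")
    names(sets) <- vapply(isos, `[[`, character(1), "iso_id")
    ev <- classify_events(graph_of(sets, isos[[1]]$strand))
    found[[g]] <- ev
  }
  all_found <- do.call(rbind, unname(found))
  expect_equal(sort(table(all_found$type)[names(sort(table(sim$events$type)))]),
               sort(table(sim$events$type)))
  expect_setequal(paste(all_found$type, all_found$coord1, all_found$coord2),
                  paste(sim$events$type, sim$events$coord1,
                        sim$events$coord2))
})

test_that("annotation-derived events: single transcripts yield none, planted pairs classify", {
  s <- small_sim(seed = 42)
  # the simulator's annotation carries one transcript per gene
  ev0 <- events_from_annotation(s$sim$annotation)
  expect_equal(nrow(ev0), 0L)
})

test_that("event-set comparison counts shared and novel events", {
  a <- classify_events(graph_of(list(x = ex(0, 100, 200, 300),
                                     y = ex(0, 300))))
  b <- a[0, ]
  cmp <- compare_event_sets(a, b)
  expect_equal(cmp$novel_a[cmp$type == "total"], 1L)
  expect_equal(cmp$shared[cmp$type == "total"], 0L)
  cmp2 <- compare_event_sets(a, a)
  expect_equal(cmp2$novel_a[cmp2$type == "total"], 0L)
  expect_equal(cmp2$shared[cmp2$type == "total"], 1L)
})

test_that("junction and isoform recall fractions", {
  mk <- function(id, exons) structure(
    list(iso_id = id, chrom = "chr1", strand = "+", exons = exons,
         introns = if (nrow(exons) > 1)
           cbind(exons[-nrow(exons), 2], exons[-1, 1])
         else matrix(integer(0), ncol = 2)),
    class = "isoform")
  ref <- list(mk("r1", ex(0, 100, 200, 300, 400, 500)))
  expect_equal(compute_assembly_recall(ref, ref),
               list(junction_recall = 1, isoform_recall = 1))
  # query missing one of the two introns
  q <- list(mk("q1", ex(0, 100, 200, 320)))
  rec <- compute_assembly_recall(ref, q)
  expect_equal(rec$junction_recall, 0.5)
  expect_equal(rec$isoform_recall, 0)
  # randomized subsets equal brute-force counting
  set.seed(5)
  s <- small_sim(seed = 42)
  all_iso <- lapply(s$sim$isoforms, function(i)
    mk(i$iso_id, i$exons))
  keep <- sample(length(all_iso), 12)
  rec2 <- compute_assembly_recall(all_iso, all_iso[keep])
  jr <- unique(unlist(lapply(all_iso, function(i)
    apply(i$introns, 1, paste, collapse = "-"))))
  jq <- unique(unlist(lapply(all_iso[keep], function(i)
    apply(i$introns, 1, paste, collapse = "-"))))
  expect_equal(rec2$junction_recall, mean(jr %in% jq))
})
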