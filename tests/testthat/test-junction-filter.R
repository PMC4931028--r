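sim_with_model <- function(seed = 21, ...) {
  s <- small_sim(seed = seed, mismatch_rate = 0, insertion_rate = 0,
                 deletion_rate = 0, ...)
  model <- train_junction_model(s$sim$annotation, s$sim$genome)
  c(s, list(model = model))
}

test_that("at least 95% of training junctions pass by threshold construction", {
  s <- sim_with_model()
  ann <- s$sim$annotation
  scores <- c()
  pass <- c()
  for (tx in unique(ann$exons$tx_id)) {
    ic <- transcript_introns(ann, tx)
    st <- ann$transcripts$strand[ann$transcripts$tx_id == tx][1]
    ch <- ann$transcripts$chrom[ann$transcripts$tx_id == tx][1]
    for (i in seq_len(nrow(ic))) {
      iv <- genomic_interval(ch, ic[i, 1], ic[i, 2], st)
      scores <- c(scores, score_junction(s$model, s$sim$genome, iv))
      pass <- c(pass, junction_passes(s$model, s$sim$genome, iv))
    }
  }
  expect_gte(mean(pass), 0.95)
  expect_gte(mean(scores >= s$model$threshold), 0.95)
})

test_that("non-canonical terminal dinucleotides are rejected regardless of score", {
  s <- sim_with_model()
  genome <- s$sim$genome
  ann <- s$sim$annotation
  tx <- ann$exons$tx_id[1]
  ic <- transcript_introns(ann, tx)
  st <- ann$transcripts$strand[ann$transcripts$tx_id == tx][1]
  ch <- ann$transcripts$chrom[ann$transcripts$tx_id == tx][1]
  iv <- genomic_interval(ch, ic[1, 1], ic[1, 2], st)
  expect_true(junction_passes(s$model, genome, iv))
  # rewrite the terminal dinucleotides to CC..GG in a genome copy
  chars <- strsplit(as.character(genome[[ch]]), "")[[1]]
  chars[(ic[1, 1] + 1):(ic[1, 1] + 2)] <- c("C", "C")
  chars[(ic[1, 2] - 1):ic[1, 2]] <- c("G", "G")
  g2 <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), ch))
  expect_false(junction_passes(s$model, g2, iv))
})

test_that("consensus junctions score at the PWM maximum; random gaps fail", {
  s <- sim_with_model()
  genome <- s$sim$genome
  ann <- s$sim$annotation
  max_attainable <- sum(apply(s$model$donor_pwm, 2, max)) +
    sum(apply(s$model$acceptor_pwm, 2, max))
  tx <- ann$exons$tx_id[1]
  ic <- transcript_introns(ann, tx)
  st <- ann$transcripts$strand[ann$transcripts$tx_id == tx][1]
  ch <- ann$transcripts$chrom[ann$transcripts$tx_id == tx][1]
  sc <- score_junction(s$model, genome,
                       genomic_interval(ch, ic[1, 1], ic[1, 2], st))
  expect_equal(sc, max_attainable, tolerance = 1e-9)

  # random intergenic gaps: >= 90% rejected (canonical gate + threshold)
  set.seed(99)
  len <- Biostrings::width(genome[1])
  fails <- replicate(200, {
    st0 <- sample(100:(len - 400), 1)
    iv <- genomic_interval("chr1", st0, st0 + sample(80:200, 1),
                           sample(c("+", "-"), 1))
    !junction_passes(s$model, genome, iv)
  })
  expect_gte(mean(fails), 0.9)
})

test_that("strand orientation changes the scored windows", {
  s <- sim_with_model()
  ann <- s$sim$annotation
  tx <- ann$exons$tx_id[1]
  ic <- transcript_introns(ann, tx)
  st <- ann$transcripts$strand[ann$transcripts$tx_id == tx][1]
  ch <- ann$transcripts$chrom[ann$transcripts$tx_id == tx][1]
  plus <- score_junction(s$model, s$sim$genome,
                         genomic_interval(ch, ic[1, 1], ic[1, 2], "+"))
  minus <- score_junction(s$model, s$sim$genome,
                          genomic_interval(ch, ic[1, 1], ic[1, 2], "-"))
  expect_false(isTRUE(all.equal(plus, minus)))
})

test_that("alignment filtering is all-or-nothing and spares unspliced reads", {
  s <- sim_with_model()
  genome <- s$sim$genome
  tr <- s$reads$alignments
  res <- filter_alignments(tr, s$model, genome)
  expect_length(res$rejected, 0L)
  # shift one junction of a spliced alignment by 4 nt -> whole read rejected
  spliced <- Filter(function(a) nrow(a$blocks) >= 2, tr)
  a <- spliced[[1]]
  a$blocks[1, 2] <- a$blocks[1, 2] + 4L
  res2 <- filter_alignments(list(a), s$model, genome)
  expect_length(res2$kept, 0L)
  unspliced <- read_aln("u1", "chr1", "+", matrix(c(10L, 60L), 1),
                        strrep("A", 50))
  expect_length(filter_alignments(list(unspliced), s$model, genome)$kept, 1L)
})

test_that("shifted-junction reads are rejected without losing true reads", {
  s <- sim_with_model(seed = 31)
  genome <- s$sim$genome
  alns <- s$reads$alignments
  spliced <- which(vapply(alns, function(a) nrow(a$blocks) >= 2, logical(1)))
  set.seed(7)
  bad <- sample(spliced, round(0.1 * length(spliced)))
  for (i in bad) {
    k <- sample(nrow(alns[[i]]$blocks) - 1L, 1L)
    alns[[i]]$blocks[k, 2L] <- alns[[i]]$blocks[k, 2L] + sample(3:8, 1)
  }
  res <- filter_alignments(alns, s$model, genome)
  rej <- vapply(res$rejected, `[[`, character(1), "qname")
  bad_ids <- vapply(alns[bad], `[[`, character(1), "qname")
  true_ids <- setdiff(vapply(alns, `[[`, character(1), "qname"), bad_ids)
  expect_gte(mean(bad_ids %in% rej), 0.9)
  expect_lte(mean(true_ids %in% rej), 0.05)
})

test_that("strand is assigned from the poly(A) tail, platform strand arbitrates", {
  plus <- read_aln("p", "chr1", "+", matrix(c(0L, 50L), 1), strrep("C", 50),
                   clip3 = strrep("A", 25))
  minus <- read_aln("m", "chr1", "-", matrix(c(0L, 50L), 1), strrep("C", 50),
                    clip5 = strrep("T", 25))
  none <- read_aln("n", "chr1", "+", matrix(c(0L, 50L), 1), strrep("C", 50))
  impure <- read_aln("i", "chr1", "+", matrix(c(0L, 50L), 1),
                     strrep("C", 50), clip3 = "ACGTACGTAC")
  expect_equal(assign_strand(plus), "+")
  expect_equal(assign_strand(minus), "-")
  expect_true(is.na(assign_strand(none)))
  expect_true(is.na(assign_strand(impure)))          # 40% A fails purity
  expect_true(is.na(assign_strand(plus, platform_strand = "-")))
  expect_equal(assign_strand(plus, platform_strand = "+"), "+")
  expect_equal(assign_strand(none, platform_strand = "-"), "-")
})

test_that("multi-mappers are separated and the cascade conserves reads", {
  s <- sim_with_model(seed = 23, frac_untailed = 0.1)
  alns <- s$reads$alignments
  alns[[1]]$n_hits <- 3L
  pm <- partition_multimappers(alns)
  expect_equal(length(pm$unique) + length(pm$multi), length(alns))
  expect_equal(pm$multi[[1]]$qname, alns[[1]]$qname)

  casc <- filter_cascade(alns, s$model, s$sim$genome,
                         unaligned = c("ghost1", "ghost2"))
  rep <- casc$report
  expect_true(all(diff(rep$reads[1:3]) <= 0))   # monotone cascade
  expect_equal(rep$reads[rep$stage == "stranded"],
               rep$reads[rep$stage == "unique"] +
                 rep$reads[rep$stage == "multi"])
  total <- length(casc$kept) + length(casc$multi) +
    length(casc$rejected_junction) + length(casc$unassignable)
  expect_equal(total, length(alns))
  expect_equal(casc$unaligned, c("ghost1", "ghost2"))
})
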