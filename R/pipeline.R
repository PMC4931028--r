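#' Pipeline configuration
#'
#' Collects paths and per-stage parameters for [run_pipeline()]. Either raw
#' reads (`reads`, FASTA) or pre-computed spliced alignments (`alignments`,
#' SAM/BAM with `N` intron and `S` soft-clip operations) must be supplied;
#' with raw reads the external aligner configured in `aligner` is invoked
#' through the iterative correction loop.
#'
#' @param genome path to the genome FASTA.
#' @param annotation path to the GFF3/GTF annotation.
#' @param out_dir output directory.
#' @param reads optional path to a reads FASTA.
#' @param alignments optional path to pre-computed SAM/BAM.
#' @param aligner an [aligner_config()]; its `max_intron` is overridden by
#'   the annotation's largest intron.
#' @param n_iterations correction iterations (0 skips correction and aligns
#'   once; ignored when `alignments` is given).
#' @param junction_mask_width junction mask half-width for the first
#'   correction round.
#' @param polya a [polya_params()].
#' @param min_tail,min_purity poly(A)-tail detection thresholds.
#' @param lncrna_variant lncRNA rule, see [classify_lncrna()].
#' @param gene_overlap_mode gene association mode, see [associate_genes()].
#' @param resume reuse cached stage outputs present in `out_dir`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome, annotation, out_dir,
                            reads = NULL, alignments = NULL,
                            aligner = aligner_config(),
                            n_iterations = 2L, junction_mask_width = 10L,
                            polya = polya_params(),
                            min_tail = 5L, min_purity = 0.8,
                            lncrna_variant = "aa100",
                            gene_overlap_mode = "exonic",
                            resume = TRUE) {
  if (is.null(reads) && is.null(alignments))
    stop("either reads or alignments must be provided")
  for (p in c(genome, annotation, reads, alignments))
    if (!file.exists(p)) stop("missing input file: ", p)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (optional) iterative align/correct, junction-model
#' training and alignment filtering, strand assignment, multi-mapper
#' separation, read clustering, isoform collapsing, representative
#' construction, gene association and full-length calling, AS-event
#' classification (read-derived vs annotation), poly(A) detection /
#' clustering / classification / APA calling, novel-locus and lncRNA
#' calling, and report generation. Stage outputs are cached in
#' `out_dir/cache` and reused when `resume = TRUE`; final artifacts are
#' written as GTF/BED/TSV under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list with all stage outputs and `summary`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  cache_dir <- file.path(out, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    f <- file.path(cache_dir, paste0(name, ".rds"))
    if (isTRUE(config$resume) && file.exists(f)) return(readRDS(f))
    v <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    saveRDS(v, f)
    v
  }

  genome <- load_genome(config$genome)
  ann <- load_annotation(config$annotation)

  alns <- stage("alignments", {
    if (!is.null(config$alignments)) read_sam(config$alignments, genome)
    else {
      reads <- setNames(as.character(Biostrings::readDNAStringSet(config$reads)),
                        sub("\\s.*$", "",
                            names(Biostrings::readDNAStringSet(config$reads))))
      cfg <- config$aligner
      cfg$max_intron <- max(ann$max_intron, 1000L)
      if (config$n_iterations >= 1L)
        iterate_correction(reads, genome, cfg, config$n_iterations,
                           config$junction_mask_width)[c("alignments",
                                                         "unaligned")]
      else run_alignment(reads, genome, cfg)
    }
  })

  model <- stage("junction_model", train_junction_model(ann, genome))
  casc <- stage("filter", filter_cascade(alns$alignments, model, genome,
                                         unaligned = alns$unaligned))
  clusters <- stage("clusters", cluster_reads(casc$kept))

  polya_reads <- stage("polya_reads", {
    rows <- lapply(casc$kept, detect_polya_tail,
                   min_tail = config$min_tail, min_purity = config$min_purity)
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))]) %||%
      data.frame(chrom = character(0), pos = integer(0),
                 strand = character(0), read_id = character(0))
  })
  site_by_read <- setNames(polya_reads$pos, polya_reads$read_id)

  isoforms <- stage("isoforms", {
    isos <- unlist(lapply(clusters, collapse_isoforms), recursive = FALSE)
    isos <- lapply(isos, build_representative, polya_sites = site_by_read)
    isos <- associate_genes(isos, ann, mode = config$gene_overlap_mode)
    lapply(isos, function(iso) {
      iso$novel <- length(iso$gene_assoc) == 0L
      iso$full_length <- length(iso$gene_assoc) == 1L &&
        classify_full_length(iso, ann)
      iso
    })
  })

  events <- stage("events", {
    # per-gene graphs over single-gene-associated isoforms
    by_gene <- split(isoforms, vapply(isoforms, function(i)
      if (length(i$gene_assoc) == 1L) i$gene_assoc else NA_character_,
      character(1)))
    by_gene <- by_gene[!is.na(names(by_gene))]
    iso_ev <- list()
    for (g in names(by_gene)) {
      isos <- by_gene[[g]]
      if (length(isos) < 2L) next
      ev <- classify_events(build_splice_graph(isos))
      if (nrow(ev)) { ev$gene_id <- g; iso_ev[[length(iso_ev) + 1L]] <- ev }
    }
    iso_events <- do.call(rbind, iso_ev)
    expressed <- unique(unlist(lapply(isoforms, `[[`, "gene_assoc")))
    ann_events <- events_from_annotation(ann, intersect(expressed,
                                                        ann$genes$gene_id))
    list(isoseq = iso_events %||% ann_events[0, ], annotation = ann_events,
         comparison = compare_event_sets(iso_events %||% ann_events[0, ],
                                         ann_events))
  })

  polya_out <- stage("polya", {
    read2gene <- list()
    for (iso in isoforms) {
      gid <- if (length(iso$gene_assoc) == 1L) iso$gene_assoc else
        iso$locus_id
      for (r in iso$read_ids) read2gene[[r]] <- gid
    }
    pr <- polya_reads
    pr$gene_id <- vapply(pr$read_id, function(r)
      read2gene[[r]] %||% NA_character_, character(1))
    pr <- pr[!is.na(pr$gene_id), , drop = FALSE]
    clusters_by_gene <- list()
    rows <- list()
    for (g in unique(pr$gene_id)) {
      sub <- pr[pr$gene_id == g, , drop = FALSE]
      cl <- cluster_polya_sites(sub$pos, config$polya)
      if (!nrow(cl)) next
      cl$gene_id <- g
      cl$chrom <- sub$chrom[1]
      cl$strand <- sub$strand[1]
      cl$region <- if (g %in% ann$genes$gene_id)
        classify_site(cl$pos, ann, g) else "unclassified"
      cl$internal_priming <- vapply(seq_len(nrow(cl)), function(i)
        detect_internal_priming(cl$pos[i], cl$chrom[i], cl$strand[i],
                                genome), logical(1))
      clusters_by_gene[[g]] <- cl
      rows[[length(rows) + 1L]] <- cl
    }
    all_cl <- do.call(rbind, rows) %||%
      data.frame(pos = integer(0), depth = integer(0),
                 members = character(0), gene_id = character(0),
                 chrom = character(0), strand = character(0),
                 region = character(0), internal_priming = logical(0))
    apa <- call_apa(clusters_by_gene)
    prof <- if (nrow(all_cl)) nucleotide_profile(all_cl, genome) else NULL
    motif <- if (nrow(all_cl))
      positional_motif_frequency(all_cl, genome) else NULL
    list(reads = pr, clusters = all_cl, by_gene = clusters_by_gene,
         apa = apa, profile = prof, motif = motif)
  })

  novel <- stage("novel", {
    iso_by_locus <- split(isoforms, vapply(isoforms, `[[`, character(1),
                                           "locus_id"))
    loci <- find_novel_loci(clusters, iso_by_locus)
    loci <- lapply(loci, function(nl) {
      seq <- spliced_sequence(genome, nl$chrom, nl$rep_blocks, nl$strand)
      nl$rep_length <- nchar(seq)
      nl$longest_orf_aa <- longest_orf(seq)$aa
      nl$lncrna <- classify_lncrna(seq, config$lncrna_variant)
      nl
    })
    list(loci = loci, anomalies = flag_gene_model_anomalies(isoforms))
  })

  result <- structure(list(config = config, genome_names = names(genome),
                           alignments = alns, filter = casc,
                           clusters = clusters, isoforms = isoforms,
                           events = events, polya = polya_out,
                           novel = novel),
                      class = "pipeline_result")
  result$summary <- summarize_pipeline(result)
  write_pipeline_outputs(result, out)
  result
}

#' Summary report of a pipeline run
#'
#' All counts are recomputed from the primary stage records; percentages
#' recompute from the counts.
#'
#' @param result a `pipeline_result`.
#' @return list of data frames: `cascade`, `as_events`, `isoforms_per_gene`,
#'   `categories`, `polya_sites_per_gene`, `apa`.
#' @export
summarize_pipeline <- function(result) {
  isoforms <- result$isoforms
  n_assoc <- vapply(isoforms, function(i) length(i$gene_assoc), integer(1))
  categories <- data.frame(
    category = c("isoforms_total", "single_gene", "no_gene", "multi_gene",
                 "intronless", "full_length", "novel"),
    count = c(length(isoforms), sum(n_assoc == 1L), sum(n_assoc == 0L),
              sum(n_assoc > 1L),
              sum(vapply(isoforms, `[[`, logical(1), "intronless")),
              sum(vapply(isoforms, function(i) isTRUE(i$full_length),
                         logical(1))),
              sum(vapply(isoforms, function(i) isTRUE(i$novel), logical(1)))))
  categories$pct <- round(100 * categories$count /
                            max(categories$count[1], 1L), 1)

  gene_of <- vapply(isoforms, function(i)
    if (length(i$gene_assoc) == 1L) i$gene_assoc else NA_character_,
    character(1))
  ipg <- table(table(gene_of[!is.na(gene_of)]))
  isoforms_per_gene <- data.frame(
    n_isoforms = as.integer(names(ipg)), n_genes = as.integer(ipg))

  types <- c("intron_retention", "exon_skipping", "alt_5prime", "alt_3prime")
  ev <- result$events
  as_events <- data.frame(
    type = c(types, "total"),
    isoseq = c(vapply(types, function(t) sum(ev$isoseq$type == t),
                      integer(1)), nrow(ev$isoseq)),
    annotation = c(vapply(types, function(t) sum(ev$annotation$type == t),
                          integer(1)), nrow(ev$annotation)))

  apa <- result$polya$apa
  spg <- if (nrow(apa)) table(apa$n_sites) else table(integer(0))
  polya_sites_per_gene <- data.frame(
    n_sites = as.integer(names(spg)), n_genes = as.integer(spg))
  cl <- result$polya$clusters
  apa_summary <- data.frame(
    metric = c("genes_with_sites", "genes_apa", "preferred_site_frac",
               "sites_total", "sites_utr3", "sites_internal", "sites_utr5",
               "sites_internal_priming"),
    value = c(nrow(apa), sum(apa$apa),
              if (sum(apa$apa)) round(mean(!is.na(
                apa$preferred_pos[apa$apa])), 3) else NA_real_,
              nrow(cl), sum(cl$region == "utr3"),
              sum(cl$region == "internal"), sum(cl$region == "utr5"),
              sum(cl$internal_priming)))

  list(cascade = result$filter$report, as_events = as_events,
       isoforms_per_gene = isoforms_per_gene, categories = categories,
       polya_sites_per_gene = polya_sites_per_gene, apa = apa_summary)
}

write_pipeline_outputs <- function(result, out) {
  write_isoforms_gtf(result$isoforms, file.path(out, "isoforms.gtf"))
  if (nrow(result$polya$clusters))
    write_polya_bed(result$polya$clusters, file.path(out, "polya_sites.bed"))
  tsv <- function(df, name) if (!is.null(df))
    write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(result$filter$report, "filter_report.tsv")
  tsv(result$events$isoseq, "as_events_isoseq.tsv")
  tsv(result$events$annotation, "as_events_annotation.tsv")
  tsv(result$events$comparison, "as_events_comparison.tsv")
  tsv(result$polya$clusters, "polya_clusters.tsv")
  tsv(result$polya$apa, "apa_summary.tsv")
  if (!is.null(result$polya$motif)) tsv(result$polya$motif, "polya_motif.tsv")
  if (!is.null(result$polya$profile))
    write.table(result$polya$profile$freq,
                file.path(out, "polya_profile.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
  for (nm in names(result$summary)) tsv(result$summary[[nm]],
                                        paste0("summary_", nm, ".tsv"))
  invisible(out)
}
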