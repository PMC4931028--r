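#' Build a splice graph from the isoforms of one locus
#'
#' Nodes are distinct exon intervals, edges the exon pairs spliced together
#' in at least one isoform, and every isoform is recorded as a path of node
#' indices.
#'
#' @param isoforms list of `isoform` objects with `exons` set, sharing one
#'   locus and strand; alternatively a list of plain exon matrices plus
#'   `chrom`/`strand` arguments.
#' @param chrom,strand required when `isoforms` is a list of exon matrices.
#' @return a `splice_graph`: `chrom`, `strand`, `nodes` (exon matrix),
#'   `edges` (two-column matrix of node indices), `paths` (list of integer
#'   vectors), `path_ids`.
#' @export
build_splice_graph <- function(isoforms, chrom = NULL, strand = NULL) {
  if (length(isoforms) == 0L) stop("no isoforms")
  if (inherits(isoforms[[1]], "isoform")) {
    strands <- unique(vapply(isoforms, `[[`, character(1), "strand"))
    if (length(strands) != 1L) stop("mixed strands in one splice graph")
    strand <- strands
    chrom <- isoforms[[1]]$chrom
    exon_sets <- lapply(isoforms, `[[`, "exons")
    ids <- vapply(isoforms, `[[`, character(1), "iso_id")
  } else {
    stopifnot(!is.null(chrom), !is.null(strand))
    exon_sets <- isoforms
    ids <- names(isoforms) %||% paste0("path", seq_along(isoforms))
  }
  all_ex <- unique(do.call(rbind, exon_sets))
  all_ex <- all_ex[order(all_ex[, 1L], all_ex[, 2L]), , drop = FALSE]
  node_key <- paste(all_ex[, 1L], all_ex[, 2L])
  paths <- lapply(exon_sets, function(ex)
    match(paste(ex[, 1L], ex[, 2L]), node_key))
  edges <- unique(do.call(rbind, lapply(paths, function(p)
    if (length(p) > 1L) cbind(p[-length(p)], p[-1L]) else NULL)))
  structure(list(chrom = chrom, strand = strand, nodes = all_ex,
                 edges = edges, paths = paths, path_ids = ids),
            class = "splice_graph")
}

#' Classify alternative-splicing events in a splice graph
#'
#' Event taxonomy:
#' \describe{
#'   \item{intron_retention}{an intron of one path is fully contained within
#'     an exon of another path; coordinates are the retained intron.}
#'   \item{exon_skipping}{an exon of one path is absent from another path
#'     that splices across it (a bridging intron fully spans the exon);
#'     coordinates are the skipped exon.}
#'   \item{alt_5prime / alt_3prime}{two introns of different paths share the
#'     acceptor but differ at the donor (alt 5'), or share the donor and
#'     differ at the acceptor (alt 3'); naming is strand-aware (the donor is
#'     the transcript-5' side). Coordinates are the two alternative junction
#'     positions plus the shared one.}
#' }
#' Events are deduplicated by (type, coordinates).
#'
#' @param graph a `splice_graph`.
#' @return data frame with columns `type`, `chrom`, `strand`, `coord1`,
#'   `coord2`, `shared`, `isoforms_a`, `isoforms_b` (comma-separated path
#'   ids on each side).
#' @export
classify_events <- function(graph) {
  paths <- graph$paths
  nodes <- graph$nodes
  path_introns <- lapply(paths, function(p)
    if (length(p) > 1L) cbind(nodes[p[-length(p)], 2L], nodes[p[-1L], 1L])
    else matrix(integer(0), ncol = 2L))
  intron_key <- function(m) paste(m[, 1L], m[, 2L])
  ik_by_path <- lapply(path_introns, intron_key)
  all_int <- unique(do.call(rbind, path_introns))
  # intron occurrences with their flanking exon nodes
  occ <- do.call(rbind, lapply(seq_along(paths), function(pi) {
    p <- paths[[pi]]
    if (length(p) < 2L) return(NULL)
    data.frame(key = ik_by_path[[pi]], path = pi,
               left = p[-length(p)], right = p[-1L])
  }))
  exon_paths <- function(node) which(vapply(paths, function(p)
    node %in% p, logical(1)))
  intron_paths <- function(key) which(vapply(ik_by_path, function(k)
    key %in% k, logical(1)))
  ev <- list()
  add <- function(type, c1, c2, shared, pa, pb)
    ev[[length(ev) + 1L]] <<- data.frame(
      type = type, chrom = graph$chrom, strand = graph$strand,
      coord1 = c1, coord2 = c2, shared = shared,
      isoforms_a = paste(graph$path_ids[pa], collapse = ","),
      isoforms_b = paste(graph$path_ids[pb], collapse = ","),
      stringsAsFactors = FALSE)

  if (!is.null(all_int) && nrow(all_int)) {
    for (i in seq_len(nrow(all_int))) {
      I <- all_int[i, ]
      pI <- intron_paths(paste(I[1], I[2]))
      for (n in seq_len(nrow(nodes))) {
        E <- nodes[n, ]
        pE <- setdiff(exon_paths(n), pI)
        if (!length(pE)) next
        # retained intron: intron inside exon
        if (E[1L] <= I[1L] && I[2L] <= E[2L])
          add("intron_retention", I[1L], I[2L], NA_integer_, pI, pE)
        # skipped exon: bridging intron spans the exon, exon absent there
        if (I[1L] <= E[1L] && E[2L] <= I[2L])
          add("exon_skipping", E[1L], E[2L], NA_integer_,
              pE, setdiff(pI, exon_paths(n)))
      }
    }
    # alternative donor/acceptor: the two introns must share one junction,
    # differ at the other, and the flanking exons on the differing side
    # must overlap (the paper's "overlapping exons" condition; this keeps a
    # skipping bridge from doubling as an alt-donor/acceptor event)
    overlaps <- function(a, b) nodes[a, 1L] < nodes[b, 2L] &&
      nodes[b, 1L] < nodes[a, 2L]
    for (i in seq_len(nrow(all_int))) for (j in seq_len(nrow(all_int))) {
      if (i >= j) next
      I1 <- all_int[i, ]; I2 <- all_int[j, ]
      k1 <- paste(I1[1], I1[2]); k2 <- paste(I2[1], I2[2])
      o1 <- occ[occ$key == k1, , drop = FALSE]
      o2 <- occ[occ$key == k2, , drop = FALSE]
      witness <- function(side) {
        for (a in seq_len(nrow(o1))) for (b in seq_len(nrow(o2)))
          if (o1$path[a] != o2$path[b] &&
              overlaps(o1[[side]][a], o2[[side]][b]))
            return(list(pa = o1$path[a], pb = o2$path[b]))
        NULL
      }
      if (I1[1L] == I2[1L] && I1[2L] != I2[2L]) {
        w <- witness("right")   # shared donor (+): acceptor-side exons
        if (!is.null(w)) {
          type <- if (graph$strand == "+") "alt_3prime" else "alt_5prime"
          add(type, min(I1[2L], I2[2L]), max(I1[2L], I2[2L]), I1[1L],
              w$pa, w$pb)
        }
      } else if (I1[2L] == I2[2L] && I1[1L] != I2[1L]) {
        w <- witness("left")    # shared acceptor (+): donor-side exons
        if (!is.null(w)) {
          type <- if (graph$strand == "+") "alt_5prime" else "alt_3prime"
          add(type, min(I1[1L], I2[1L]), max(I1[1L], I2[1L]), I1[2L],
              w$pa, w$pb)
        }
      }
    }
  }
  if (!length(ev))
    return(data.frame(type = character(0), chrom = character(0),
                      strand = character(0), coord1 = integer(0),
                      coord2 = integer(0), shared = integer(0),
                      isoforms_a = character(0), isoforms_b = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, ev)
  out <- out[!is.na(out$isoforms_b) & nzchar(out$isoforms_b) |
             out$type %in% c("intron_retention"), , drop = FALSE]
  key <- event_key(out)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

event_key <- function(ev)
  paste(ev$type, ev$chrom, ev$strand, ev$coord1, ev$coord2,
        ifelse(is.na(ev$shared), "", ev$shared))

#' Classify AS events present in an annotation
#'
#' Builds a splice graph per gene from the annotated transcripts and runs
#' [classify_events()]; genes with a single transcript contribute no events.
#'
#' @param ann an `annotation_index`.
#' @param gene_ids optional subset of genes (e.g., the expressed ones).
#' @return combined event data frame with a `gene_id` column.
#' @export
events_from_annotation <- function(ann, gene_ids = NULL) {
  gene_ids <- gene_ids %||% ann$genes$gene_id
  out <- list()
  for (g in gene_ids) {
    txs <- ann$transcripts$tx_id[ann$transcripts$gene_id == g]
    if (length(txs) < 2L) next
    exon_sets <- lapply(txs, function(t) transcript_exons(ann, t))
    names(exon_sets) <- txs
    gr <- build_splice_graph(exon_sets,
                             chrom = ann$genes$chrom[ann$genes$gene_id == g],
                             strand = ann$genes$strand[ann$genes$gene_id == g])
    ev <- classify_events(gr)
    if (nrow(ev)) { ev$gene_id <- g; out[[length(out) + 1L]] <- ev }
  }
  if (!length(out)) {
    e <- classify_events(structure(list(chrom = "", strand = "+",
                                        nodes = matrix(0, 0, 2),
                                        edges = NULL, paths = list(),
                                        path_ids = character(0)),
                                   class = "splice_graph"))
    e$gene_id <- character(0)
    return(e)
  }
  do.call(rbind, out)
}

#' Compare two AS-event sets
#'
#' Events are matched by (type, chromosome, strand, defining coordinates).
#'
#' @param events_a,events_b event data frames from [classify_events()].
#' @return data frame per type (plus `total`): `shared`, `novel_a`
#'   (in A only), `novel_b` (in B only).
#' @export
compare_event_sets <- function(events_a, events_b) {
  ka <- event_key(events_a); kb <- event_key(events_b)
  types <- c("intron_retention", "exon_skipping", "alt_5prime", "alt_3prime")
  rows <- lapply(types, function(t) {
    a <- unique(ka[events_a$type == t]); b <- unique(kb[events_b$type == t])
    data.frame(type = t, shared = length(intersect(a, b)),
               novel_a = length(setdiff(a, b)),
               novel_b = length(setdiff(b, a)))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(type = "total", shared = sum(out$shared),
                        novel_a = sum(out$novel_a),
                        novel_b = sum(out$novel_b)))
}

#' Junction- and isoform-level recall of a reference set in a query set
#'
#' Junction recall is the fraction of distinct reference introns present in
#' the query; isoform recall is the fraction of spliced reference isoforms
#' whose full intron chain appears exactly as the chain of some query
#' transcript.
#'
#' @param reference,query lists of `isoform` objects (or any objects with
#'   `chrom`, `strand` and `introns` fields).
#' @return list with `junction_recall` and `isoform_recall` fractions.
#' @export
compute_assembly_recall <- function(reference, query) {
  jset <- function(isos) unique(unlist(lapply(isos, function(x) {
    ic <- x$introns
    if (!nrow(ic)) return(character(0))
    paste(x$chrom, ic[, 1L], ic[, 2L])
  })))
  cset <- function(isos) unique(vapply(isos, function(x)
    paste(x$chrom, x$strand, chain_key(x$introns)), character(1)))
  rj <- jset(reference); qj <- jset(query)
  spliced <- Filter(function(x) nrow(x$introns) > 0L, reference)
  rc <- cset(spliced); qc <- cset(query)
  list(junction_recall = if (length(rj)) mean(rj %in% qj) else NA_real_,
       isoform_recall = if (length(rc)) mean(rc %in% qc) else NA_real_)
}
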