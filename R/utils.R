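#' @importFrom stats quantile rbinom rgeom rnorm runif setNames
#' @importFrom utils head read.delim tail write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over {A,C,G,T,N}.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Genomic interval in 0-based half-open coordinates
#'
#' All internal coordinates in the package are 0-based half-open; 1-based
#' inclusive coordinates appear only at the GFF/GTF boundary.
#'
#' @param chrom chromosome name (non-empty).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unknown).
#' @return a `genomic_interval` list.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ",", end, ")")
  if (!strand %in% c("+", "-", "*")) stop("strand must be one of '+', '-', '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

# ordered intron chain (0-based half-open) from a sorted exon matrix
introns_from_exons <- function(exons) {
  if (nrow(exons) < 2L) return(matrix(integer(0), ncol = 2L,
                                      dimnames = list(NULL, c("start", "end"))))
  cbind(start = exons[-nrow(exons), 2L], end = exons[-1L, 1L])
}

chain_key <- function(introns) {
  if (is.null(introns) || nrow(introns) == 0L) return("")
  paste(paste(introns[, 1L], introns[, 2L], sep = "-"), collapse = ";")
}

# stable textual id helpers
pad_id <- function(prefix, i, width = 5L) sprintf("%s%0*d", prefix, width, i)
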