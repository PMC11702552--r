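#' Construct and validate a gene coordinate table
#'
#' Coordinates are 0-based, half-open throughout the package (BED
#' convention). The TSS of a minus-strand gene is its larger coordinate.
#'
#' @param gene_id character vector of gene identifiers (unique).
#' @param chrom character vector of chromosome names.
#' @param gene_start,gene_end integer vectors, 0-based half-open span.
#' @param strand character vector, "+" or "-".
#' @param tss optional integer vector of transcription start sites; if
#'   missing, set to `gene_start` for "+" genes and `gene_end` for "-".
#' @return data.frame with columns gene_id, chrom, gene_start, gene_end,
#'   strand, tss.
#' @export
gene_table <- function(gene_id, chrom, gene_start, gene_end, strand,
                       tss = NULL) {
  gene_start <- as.integer(gene_start)
  gene_end <- as.integer(gene_end)
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (any(gene_start >= gene_end)) stop("gene_start must be < gene_end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(tss)) {
    tss <- ifelse(strand == "+", gene_start, gene_end)
  }
  tss <- as.integer(tss)
  if (any(tss < 0)) stop("tss must be >= 0")
  data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    gene_start = gene_start, gene_end = gene_end,
    strand = as.character(strand), tss = tss,
    stringsAsFactors = FALSE
  )
}

#' Promoter window around the TSS
#'
#' Returns the promoter interval covering `upstream` bp upstream and
#' `downstream` bp downstream of the TSS, strand-aware, in 0-based
#' half-open coordinates. For minus-strand genes the genomic interval is
#' mirrored and the caller is expected to reverse-complement the
#' extracted sequence. Intervals are truncated at the chromosome start
#' (never negative).
#'
#' @param genes data.frame as returned by [gene_table()] (columns chrom,
#'   tss, strand at minimum).
#' @param upstream,downstream window sizes in bp; defaults 1000 and 500.
#' @return data.frame with columns chrom, start, end, strand (and
#'   gene_id if present in the input).
#' @examples
#' g <- gene_table("g1", "chr1", 4500, 8000, "+", tss = 5000)
#' promoter_window(g)  # [4000, 5500)
#' @export
promoter_window <- function(genes, upstream = 1000, downstream = 500) {
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("unknown strand; must be '+' or '-'")
  }
  if (any(genes$tss < 0)) stop("tss must be >= 0")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  start <- pmax(start, 0L)
  out <- data.frame(
    chrom = genes$chrom, start = as.integer(start), end = as.integer(end),
    strand = genes$strand, stringsAsFactors = FALSE
  )
  if (!is.null(genes$gene_id)) out <- cbind(gene_id = genes$gene_id, out)
  out
}
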