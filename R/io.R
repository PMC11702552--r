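## Readers/writers for the pipeline's plain-text interchange formats.
## All genomic coordinates are 0-based half-open (BED convention);
## readers assert the columns they need and report offending line
## numbers (1-based, counting the header) on malformed input.

.check_numeric_col <- function(x, col, file, integer = FALSE) {
  suppr <- suppressWarnings(if (integer) {
    v <- as.numeric(x)
    bad <- is.na(v) | v != floor(v)
    v
  } else {
    v <- as.numeric(x)
    bad <- is.na(v) & !is.na(x)
    v
  })
  if (any(bad)) {
    stop(sprintf("%s: column '%s' malformed at line %d",
                 file, col, which(bad)[1] + 1L))
  }
  if (integer) as.integer(suppr) else suppr
}

#' Read / write long-format expression tables
#'
#' The expression interchange format is a TSV with header columns
#' `gene_id, genotype_id, replicate, time_h, count, norm_value`; one row
#' per observation. `count` may be NA when only normalized values are
#' available.
#'
#' @param path file path.
#' @return data.frame with the six columns, `time_h`/`norm_value`
#'   numeric, `replicate` integer.
#' @export
read_expression_tsv <- function(path) {
  x <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("gene_id", "genotype_id", "replicate", "time_h", "count",
            "norm_value")
  if (!all(need %in% names(x))) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(setdiff(need, names(x)), collapse = ", ")))
  }
  x$replicate <- .check_numeric_col(x$replicate, "replicate", path,
                                    integer = TRUE)
  x$time_h <- .check_numeric_col(x$time_h, "time_h", path)
  x$count <- suppressWarnings(as.numeric(x$count))
  x$norm_value <- .check_numeric_col(x$norm_value, "norm_value", path)
  if (any(x$norm_value < 0, na.rm = TRUE)) {
    stop(sprintf("%s: negative norm_value at line %d", path,
                 which(x$norm_value < 0)[1] + 1L))
  }
  x[need]
}

#' @rdname read_expression_tsv
#' @param expr data.frame in the expression long format.
#' @export
write_expression_tsv <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene tables as BED6
#'
#' BED6 columns: chrom, start, end, name, score, strand; 0-based
#' half-open. On read, the TSS is reconstructed from the strand (start
#' for "+", end for "-").
#'
#' @param path file path.
#' @return data.frame as from [gene_table()].
#' @export
read_genes_bed <- function(path) {
  x <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(x) < 6) stop(sprintf("%s: BED6 requires 6 columns", path))
  start <- .check_numeric_col(x[[2]], "start", path, integer = TRUE)
  end <- .check_numeric_col(x[[3]], "end", path, integer = TRUE)
  gene_table(x[[4]], x[[1]], start, end, x[[6]])
}

#' @rdname read_genes_bed
#' @param genes gene table.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$gene_start, genes$gene_end,
                    genes$gene_id, 0L, genes$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write promoter haplotype assignments
#'
#' TSV with header `pangene_id, genotype_id, haplotype_id`; one
#' haplotype per (pangene, genotype).
#'
#' @param path file path.
#' @return data.frame with the three character columns.
#' @export
read_haplotypes_tsv <- function(path) {
  x <- read.delim(path, colClasses = "character")
  need <- c("pangene_id", "genotype_id", "haplotype_id")
  if (!all(need %in% names(x))) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(setdiff(need, names(x)), collapse = ", ")))
  }
  if (anyDuplicated(x[c("pangene_id", "genotype_id")])) {
    stop(sprintf("%s: duplicate (pangene, genotype) assignment", path))
  }
  x[need]
}

#' @rdname read_haplotypes_tsv
#' @param haps haplotype table.
#' @export
write_haplotypes_tsv <- function(haps, path) {
  write.table(haps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write SNP tables
#'
#' TSV with header `snp_id, chrom, pos, maf, pvalue` (pvalue may be NA)
#' plus optional per-individual genotype dosage columns (0/1/2, NA for
#' missing). Positions are 0-based and must be sorted within chromosome.
#'
#' @param path file path.
#' @return data.frame; genotype columns (if any) keep their names.
#' @export
read_snps_tsv <- function(path) {
  x <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("snp_id", "chrom", "pos", "maf")
  if (!all(need %in% names(x))) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(setdiff(need, names(x)), collapse = ", ")))
  }
  x$pos <- .check_numeric_col(x$pos, "pos", path, integer = TRUE)
  x$maf <- .check_numeric_col(x$maf, "maf", path)
  if (any(x$maf <= 0 | x$maf > 0.5)) {
    stop(sprintf("%s: maf out of (0, 0.5] at line %d", path,
                 which(x$maf <= 0 | x$maf > 0.5)[1] + 1L))
  }
  if ("pvalue" %in% names(x)) {
    x$pvalue <- suppressWarnings(as.numeric(x$pvalue))
    bad <- !is.na(x$pvalue) & (x$pvalue <= 0 | x$pvalue > 1)
    if (any(bad)) {
      stop(sprintf("%s: pvalue out of (0, 1] at line %d", path,
                   which(bad)[1] + 1L))
    }
  }
  geno_cols <- setdiff(names(x), c(need, "pvalue"))
  for (g in geno_cols) x[[g]] <- suppressWarnings(as.numeric(x[[g]]))
  for (chr in unique(x$chrom)) {
    p <- x$pos[x$chrom == chr]
    if (is.unsorted(p)) {
      stop(sprintf("%s: positions not sorted within %s", path, chr))
    }
  }
  x
}

#' @rdname read_snps_tsv
#' @param snps SNP table.
#' @export
write_snps_tsv <- function(snps, path) {
  write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal VCF reader
#'
#' Reads CHROM, POS, ID, REF, ALT and per-sample GT only, converting
#' genotypes to additive dosage of the ALT allele (0/1/2, NA for
#' missing). VCF POS is 1-based; it is converted to the package's
#' 0-based convention.
#'
#' @param path VCF file (plain or bgzipped).
#' @return data.frame with columns snp_id, chrom, pos (0-based), ref,
#'   alt, then one dosage column per sample.
#' @export
read_vcf_lite <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- apply(gt, 2, function(col) {
    a <- gsub("\\|", "/", col)
    vapply(strsplit(a, "/"), function(al) {
      if (any(al %in% c(".", "")) || length(al) == 0) return(NA_real_)
      sum(al != "0")
    }, numeric(1))
  })
  out <- data.frame(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(dosage))
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings. Sequences are uppercased on read so
#' soft-masked (lowercase) bases are treated like their uppercase
#' counterparts.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L
  )
  invisible(path)
}

#' Write / read motifs in MEME minimal format
#'
#' @param motifs list of motif objects as from [new_motif_pfm()].
#' @param path output file.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(m$pfm), m$n_sites), con)
    apply(m$pfm, 2, function(col) {
      writeLines(paste(sprintf("%.6f", col), collapse = " "), con)
    })
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  motifs <- list()
  for (s in starts) {
    name <- sub("^MOTIF\\s+", "", lines[s])
    name <- strsplit(name, "\\s+")[[1]][1]
    hdr <- s + 1L
    while (!grepl("^letter-probability matrix", lines[hdr])) hdr <- hdr + 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    ns <- if (grepl("nsites=", lines[hdr])) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr]))
    } else NA_integer_
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4))
    dimnames(mat) <- NULL
    motifs[[name]] <- new_motif_pfm(mat, name = name, n_sites = ns)
  }
  motifs
}

#' Construct a position frequency matrix motif
#'
#' @param pfm 4 x W numeric matrix of column-stochastic base
#'   probabilities, rows in A, C, G, T order.
#' @param name motif name.
#' @param n_sites number of sites the PFM was built from.
#' @return list with class "motif_pfm".
#' @export
new_motif_pfm <- function(pfm, name = "motif", n_sites = NA_integer_) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4) stop("pfm must have 4 rows (A, C, G, T)")
  if (ncol(pfm) < 4) stop("pfm width must be >= 4")
  csum <- colSums(pfm)
  if (any(abs(csum - 1) > 1e-9)) stop("pfm columns must sum to 1")
  rownames(pfm) <- c("A", "C", "G", "T")
  structure(list(pfm = pfm, name = name, n_sites = n_sites),
            class = "motif_pfm")
}
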