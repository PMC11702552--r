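## Enrichment of candidate gene sets for GWAS and adaptation signal,
## per-site Weir-Cockerham Fst, Fisher's combined test, and the
## night-day cis-eQTL / GWAS matched-overlap test. All permutation
## p-values use the bias-safe (1 + #extreme) / (1 + n) estimator and
## are deterministic under a seed; sampled tests switch to exhaustive
## enumeration when the number of distinct null samples is small.

#' Minimum GWAS p-value in a gene's flanked window
#'
#' For each gene, the smallest SNP association p-value within
#' `[gene_start - flank, gene_end + flank)` on the gene's chromosome.
#' Genes with no SNP in the window get NA.
#'
#' @param genes gene table (columns gene_id, chrom, gene_start,
#'   gene_end).
#' @param snps SNP table (columns chrom, pos, pvalue).
#' @param flank window flank in bp (default 1000).
#' @return named numeric vector of minimum p-values, one per gene.
#' @export
gene_min_gwas_p <- function(genes, snps, flank = 1000) {
  out <- vapply(seq_len(nrow(genes)), function(i) {
    sel <- snps$chrom == genes$chrom[i] &
      snps$pos >= genes$gene_start[i] - flank &
      snps$pos < genes$gene_end[i] + flank &
      !is.na(snps$pvalue)
    if (!any(sel)) NA_real_ else min(snps$pvalue[sel])
  }, numeric(1))
  setNames(out, genes$gene_id)
}

.perm_p <- function(observed, null_stats, direction, strict = FALSE) {
  extreme <- switch(direction,
    lower_is_enriched = if (strict) null_stats < observed
                        else null_stats <= observed,
    higher_is_enriched = if (strict) null_stats > observed
                         else null_stats >= observed,
    stop("unknown direction"))
  (1 + sum(extreme)) / (1 + length(null_stats))
}

.enrichment_result <- function(observed, null_stats, direction,
                               null_set_name, strict = FALSE,
                               extra = list()) {
  structure(c(list(
    observed_stat = observed, null_stats = null_stats,
    pvalue = .perm_p(observed, null_stats, direction, strict),
    direction = direction, null_set_name = null_set_name
  ), extra), class = "enrichment_result")
}

#' @exportS3Method base::print
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Permutation enrichment vs '%s': observed = %.4g, p = %.4g (%s, %d null samples)\n",
    x$null_set_name, x$observed_stat, x$pvalue, x$direction,
    length(x$null_stats)))
  invisible(x)
}

.null_combinations <- function(null_ids, m, n_samples, seed,
                               exhaustive_limit) {
  n <- length(null_ids)
  n_comb <- choose(n, m)
  if (n_comb <= exhaustive_limit) {
    list(draws = combn(null_ids, m, simplify = FALSE), exact = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    list(draws = replicate(n_samples, sample(null_ids, m),
                           simplify = FALSE), exact = FALSE)
  }
}

#' Gene-set enrichment for GWAS signal (mean of per-gene minimum p)
#'
#' The observed statistic is the mean, over the candidate genes, of the
#' minimum GWAS p-value within each gene +/- `flank` bp. It is compared
#' to the same statistic on `n_samples` random draws of equally many
#' genes from a null set (without replacement); lower means are
#' enriched. Genes with no SNP in their window are dropped from the
#' mean (count reported). When the number of distinct null draws is at
#' most `exhaustive_limit`, all of them are enumerated instead of
#' sampled.
#'
#' @param candidates character vector of candidate gene ids.
#' @param null_ids character vector of null-set gene ids (at least as
#'   many as candidates).
#' @param genes gene table covering candidates and null set.
#' @param snps SNP table with GWAS `pvalue`.
#' @param flank flank in bp (default 1000).
#' @param n_samples number of null samples (default 1000).
#' @param seed optional integer seed.
#' @param null_set_name label carried into the result.
#' @param exhaustive_limit enumeration switch (default 5000).
#' @return "enrichment_result": observed_stat, null_stats, pvalue,
#'   direction, null_set_name, n_candidates_scored, exact.
#' @export
gwas_enrichment <- function(candidates, null_ids, genes, snps,
                            flank = 1000, n_samples = 1000, seed = NULL,
                            null_set_name = "null",
                            exhaustive_limit = 5000) {
  m <- length(candidates)
  if (length(null_ids) < m) stop("null set smaller than candidate set")
  all_ids <- union(candidates, null_ids)
  minp <- gene_min_gwas_p(genes[match(all_ids, genes$gene_id), ],
                          snps, flank)
  stat <- function(ids) mean(minp[ids], na.rm = TRUE)
  observed <- stat(candidates)
  cmb <- .null_combinations(null_ids, m, n_samples, seed,
                            exhaustive_limit)
  null_stats <- vapply(cmb$draws, stat, numeric(1))
  .enrichment_result(observed, null_stats, "lower_is_enriched",
                     null_set_name, strict = FALSE,
                     extra = list(
                       n_candidates_scored = sum(!is.na(minp[candidates])),
                       exact = cmb$exact))
}

#' Adaptation-SNP overlap enrichment
#'
#' Counts adaptation-candidate SNPs falling inside candidate gene
#' windows (gene +/- `flank` bp, half-open; a SNP in several windows
#' counts once) and compares to equally sized random gene draws from a
#' null set. More overlap is enrichment; the p-value is the bias-safe
#' proportion of null samples with at least as many overlapping SNPs
#' (ties count toward the null, so a degenerate all-zero overlap gives
#' p = 1 rather than spurious enrichment).
#'
#' @param adaptation_snps SNP table of putative adaptation variants
#'   (columns chrom, pos).
#' @inheritParams gwas_enrichment
#' @return "enrichment_result" with direction higher_is_enriched.
#' @export
adaptation_overlap_enrichment <- function(candidates, adaptation_snps,
                                          null_ids, genes, flank = 1000,
                                          n_samples = 1000, seed = NULL,
                                          null_set_name = "null",
                                          exhaustive_limit = 5000) {
  m <- length(candidates)
  if (length(null_ids) < m) stop("null set smaller than candidate set")
  overlap_count <- function(ids) {
    g <- genes[match(ids, genes$gene_id), ]
    hit <- rep(FALSE, nrow(adaptation_snps))
    for (i in seq_len(nrow(g))) {
      hit <- hit | (adaptation_snps$chrom == g$chrom[i] &
                      adaptation_snps$pos >= g$gene_start[i] - flank &
                      adaptation_snps$pos < g$gene_end[i] + flank)
    }
    sum(hit)
  }
  observed <- overlap_count(candidates)
  cmb <- .null_combinations(null_ids, m, n_samples, seed,
                            exhaustive_limit)
  null_stats <- vapply(cmb$draws, overlap_count, numeric(1))
  .enrichment_result(observed, null_stats, "higher_is_enriched",
                     null_set_name, strict = FALSE,
                     extra = list(exact = cmb$exact))
}

#' Standard null gene sets for enrichment testing
#'
#' Builds the four null sets used by the enrichment stage from the
#' rhythmicity scan: all genes; transcribed genes (MESOR above
#' `transcribed_floor` in at least one inbred); genes cycling (p below
#' `cycling_alpha`) in at least 2 inbreds; and genes cycling in at least
#' `high_cycling_min` inbreds.
#'
#' @param rhythm output of [rhythm_scan()].
#' @param cycling_alpha rhythmicity threshold (default 0.01).
#' @param transcribed_floor MESOR floor for "transcribed" (default 5).
#' @param high_cycling_min inbred count for near-constitutive cycling
#'   (default 22).
#' @return named list of gene-id character vectors: all_genes,
#'   transcribed, cycling_ge2, cycling_ge22.
#' @export
null_gene_sets <- function(rhythm, cycling_alpha = 0.01,
                           transcribed_floor = 5,
                           high_cycling_min = 22) {
  genes <- unique(rhythm$gene_id)
  n_cyc <- tapply(rhythm$pvalue < cycling_alpha, rhythm$gene_id, sum)
  max_m <- tapply(rhythm$M, rhythm$gene_id, max)
  list(
    all_genes = genes,
    transcribed = names(max_m)[max_m > transcribed_floor],
    cycling_ge2 = names(n_cyc)[n_cyc >= 2],
    cycling_ge22 = names(n_cyc)[n_cyc >= high_cycling_min]
  )
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values as `X = -2 * sum(log(p))`, referred
#' to a chi-square with 2k degrees of freedom.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return combined p-value.
#' @export
fisher_combined <- function(pvalues) {
  if (length(pvalues) == 0) stop("no p-values")
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must be in (0, 1]")
  x <- -2 * sum(log(pvalues))
  pchisq(x, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Per-site Weir-Cockerham Fst between two populations
#'
#' Variance-components estimator for two populations of diploids from
#' additive dosages (0/1/2 copies of the alternate allele, NA missing).
#' Returns the a, b, c components and `fst = a / (a + b + c)` per site;
#' sites monomorphic across both populations (or with a zero total
#' variance decomposition) are NA. Estimates can be negative near zero
#' differentiation.
#'
#' @param dosages_pop1,dosages_pop2 numeric matrices, SNPs x
#'   individuals (a vector is treated as one SNP).
#' @return data.frame with columns a, b, c, fst, one row per SNP.
#' @export
weir_cockerham_fst <- function(dosages_pop1, dosages_pop2) {
  as_mat <- function(d) if (is.null(dim(d))) matrix(d, nrow = 1) else as.matrix(d)
  d1 <- as_mat(dosages_pop1); d2 <- as_mat(dosages_pop2)
  if (nrow(d1) != nrow(d2)) stop("populations must cover the same SNPs")
  r <- 2
  out <- t(vapply(seq_len(nrow(d1)), function(i) {
    x1 <- d1[i, ]; x1 <- x1[!is.na(x1)]
    x2 <- d2[i, ]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) return(c(NA, NA, NA, NA))
    p1 <- mean(x1) / 2; p2 <- mean(x2) / 2
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) return(c(NA, NA, NA, NA))
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    tot <- a + b + cc
    c(a, b, cc, if (tot == 0) NA else a / tot)
  }, numeric(4)))
  out <- as.data.frame(out)
  names(out) <- c("a", "b", "c", "fst")
  out
}

#' Keep the top-k SNPs by Fst
#'
#' Orders scored SNPs by decreasing Fst and keeps the first `k` (all if
#' fewer are scored); ties at the cutoff are broken by genomic order
#' (chromosome, then position). NA Fst values are dropped.
#'
#' @param snps SNP table with columns chrom, pos.
#' @param fst numeric vector of per-SNP Fst aligned with `snps` rows.
#' @param k number to keep (default 10000).
#' @return subset of `snps` rows, with an `fst` column, in ranked order.
#' @export
top_k_snps <- function(snps, fst, k = 10000) {
  if (length(fst) != nrow(snps)) stop("fst must align with snps rows")
  keep <- !is.na(fst)
  if (!any(keep)) stop("no scored SNPs")
  s <- snps[keep, , drop = FALSE]
  s$fst <- fst[keep]
  ord <- order(-s$fst, s$chrom, s$pos)
  s[ord[seq_len(min(k, nrow(s)))], , drop = FALSE]
}

#' Night minus day expression response
#'
#' Per-individual difference between nighttime and daytime expression
#' estimates; NA if either is missing.
#'
#' @param night,day numeric vectors (matched by names when both are
#'   named, else by position).
#' @return numeric vector of night - day differences.
#' @export
night_day_response <- function(night, day) {
  if (!is.null(names(night)) && !is.null(names(day))) {
    ids <- union(names(night), names(day))
    night <- night[ids]; day <- day[ids]
    out <- setNames(as.numeric(night) - as.numeric(day), ids)
  } else {
    if (length(night) != length(day)) stop("unmatched individuals")
    out <- night - day
  }
  out
}

#' Cis-eQTL scan by per-SNP linear regression
#'
#' Regresses a per-individual response (typically the night-day
#' difference) on additive dosage for every SNP within `window` bp of
#' the focal gene span; two-sided t-test p-values. Individuals missing
#' either value are dropped per SNP; monomorphic SNPs are skipped.
#'
#' @param response named numeric vector (names = individual ids).
#' @param snps SNP table whose genotype columns are individual ids.
#' @param gene one-row gene table for the focal gene.
#' @param window cis window in bp (default 5000).
#' @return data.frame: snp_id, beta, t, pvalue, n (NA rows for skipped
#'   monomorphic SNPs).
#' @export
cis_eqtl_scan <- function(response, snps, gene, window = 5000) {
  inds <- intersect(names(response), names(snps))
  if (length(inds) < 10) stop("need >= 10 individuals with genotype and response")
  sel <- snps$chrom == gene$chrom &
    snps$pos >= gene$gene_start - window &
    snps$pos < gene$gene_end + window
  s <- snps[sel, , drop = FALSE]
  rows <- lapply(seq_len(nrow(s)), function(i) {
    g <- as.numeric(s[i, inds])
    y <- as.numeric(response[inds])
    ok <- !is.na(g) & !is.na(y)
    g <- g[ok]; y <- y[ok]
    n <- length(g)
    if (n < 3 || length(unique(g)) < 2) {
      return(data.frame(snp_id = s$snp_id[i], beta = NA_real_,
                        t = NA_real_, pvalue = NA_real_, n = n))
    }
    gx <- g - mean(g); yx <- y - mean(y)
    beta <- sum(gx * yx) / sum(gx^2)
    rss <- sum((yx - beta * gx)^2)
    se <- sqrt(rss / (n - 2) / sum(gx^2))
    tv <- if (se == 0) sign(beta) * Inf else beta / se
    data.frame(snp_id = s$snp_id[i], beta = beta, t = tv,
               pvalue = 2 * pt(-abs(tv), df = n - 2), n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance from each SNP to the nearest gene
#'
#' 0 for SNPs inside a gene span; otherwise the bp gap to the closest
#' span on the same chromosome (Inf if the chromosome has no gene).
#'
#' @param snps SNP table (chrom, pos).
#' @param genes gene table.
#' @return numeric vector of distances.
#' @export
snp_gene_distance <- function(snps, genes) {
  vapply(seq_len(nrow(snps)), function(i) {
    g <- genes[genes$chrom == snps$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(Inf)
    d <- pmax(g$gene_start - snps$pos[i], snps$pos[i] - (g$gene_end - 1), 0)
    min(d)
  }, numeric(1))
}

.maf_bins <- function(maf) {
  br <- unique(quantile(maf, probs = seq(0, 1, 0.1), names = FALSE))
  if (length(br) < 2) return(rep(1L, length(maf)))
  as.integer(cut(maf, breaks = br, include.lowest = TRUE))
}

.dist_bins <- function(d) {
  ifelse(d == 0, 1L,
    1L + as.integer(cut(d, breaks = c(0, 500, 1000, 2500, 5000, Inf))))
}

#' Matched-null overlap test between cis-eQTL and GWAS hits
#'
#' Counts how many cis-eQTL SNPs are GWAS hits (association p-value
#' below `gwas_hit_p`) and compares to random draws that sample, for
#' every eQTL SNP, a SNP from the same stratum of minor allele
#' frequency (deciles over all SNPs) crossed with distance to the
#' nearest gene (bins 0, (0,500], (500,1000], (1000,2500], (2500,5000],
#' >5000 bp). Strata with no eligible SNP are widened to neighboring
#' MAF bins with a warning.
#'
#' @param eqtl_snp_ids character vector of cis-eQTL SNP ids (must be
#'   rows of `snps`).
#' @param snps SNP table with maf and GWAS pvalue.
#' @param genes gene table (for distance-to-nearest-gene matching).
#' @param gwas_hit_p GWAS hit threshold (default 1e-5).
#' @param n_draws matched draws (default 10000).
#' @param seed optional integer seed.
#' @return "enrichment_result" with direction higher_is_enriched.
#' @export
matched_overlap_test <- function(eqtl_snp_ids, snps, genes,
                                 gwas_hit_p = 1e-5, n_draws = 10000,
                                 seed = NULL) {
  if (!all(eqtl_snp_ids %in% snps$snp_id)) {
    stop("all eQTL SNPs must be present in the SNP table")
  }
  dist <- snp_gene_distance(snps, genes)
  mbin <- .maf_bins(snps$maf)
  dbin <- .dist_bins(dist)
  hit <- !is.na(snps$pvalue) & snps$pvalue < gwas_hit_p
  ei <- match(eqtl_snp_ids, snps$snp_id)
  observed <- sum(hit[ei])
  if (!is.null(seed)) set.seed(seed)
  null_counts <- numeric(n_draws)
  for (j in seq_along(ei)) {
    i <- ei[j]
    pool <- which(mbin == mbin[i] & dbin == dbin[i])
    widen <- 1L
    while (length(pool) == 0) {
      warning(sprintf("empty matching stratum for %s; widening MAF bin",
                      snps$snp_id[i]))
      pool <- which(abs(mbin - mbin[i]) <= widen & dbin == dbin[i])
      widen <- widen + 1L
    }
    draws <- pool[sample.int(length(pool), n_draws, replace = TRUE)]
    null_counts <- null_counts + hit[draws]
  }
  .enrichment_result(observed, null_counts, "higher_is_enriched",
                     "matched_snps", strict = FALSE)
}
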