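## Differential Diel Regulation (DDR): pan-genes whose diel expression
## range co-segregates with promoter haplotype. The association response
## is the diel range (max - min abundance across the 24-h course); the
## test is a Kruskal-Wallis statistic on haplotype groups with a
## label-permutation null. Ranks are invariant under label permutation,
## so the permutation null reduces to re-summing a fixed rank vector
## over permuted group indicators — done as a single matrix product.

#' Diel range of an expression series
#'
#' Difference between the maximum and minimum abundance over the time
#' course. Replicates are averaged per timepoint first.
#'
#' @param times numeric sampling times (hours).
#' @param values numeric abundances, same length.
#' @return numeric scalar; 0 for a single timepoint.
#' @export
diel_range <- function(times, values) {
  if (length(values) == 0) stop("empty series")
  m <- tapply(values, times, mean)
  max(m) - min(m)
}

.kw_h_from_ranksums <- function(rank_sums, n_g, N, tie_c) {
  h <- 12 / (N * (N + 1)) * sum(rank_sums^2 / n_g) - 3 * (N + 1)
  if (tie_c <= 0) 0 else h / tie_c
}

#' Kruskal-Wallis H statistic
#'
#' Rank-based H with the standard tie correction; defined as 0 when all
#' values are identical. Matches `stats::kruskal.test()`.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor), >= 2 groups.
#' @return numeric H.
#' @export
kw_statistic <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  N <- length(values)
  r <- rank(values)
  tie_t <- table(values)
  tie_c <- 1 - sum(tie_t^3 - tie_t) / (N^3 - N)
  rs <- tapply(r, groups, sum)
  .kw_h_from_ranksums(rs, as.vector(table(groups)), N, tie_c)
}

.n_assignments <- function(n_g) {
  exp(lgamma(sum(n_g) + 1) - sum(lgamma(n_g + 1)))
}

## Enumerate every distinct assignment of group sizes n_g to N positions
## and return the H statistic of each.
.kw_exhaustive_h <- function(r, n_g, N, tie_c) {
  k <- length(n_g)
  out <- numeric(0)
  recurse <- function(avail, sizes, sums) {
    if (length(sizes) == 1) {
      out[[length(out) + 1]] <<- .kw_h_from_ranksums(
        c(sums, sum(r[avail])), n_g, N, tie_c)
      return(invisible())
    }
    ch <- combn(avail, sizes[1])
    for (j in seq_len(ncol(ch))) {
      pick <- ch[, j]
      recurse(setdiff(avail, pick), sizes[-1], c(sums, sum(r[pick])))
    }
  }
  recurse(seq_len(N), n_g, numeric(0))
  unlist(out)
}

#' Permutation p-value for the Kruskal-Wallis statistic
#'
#' Estimates `P(H_perm >= H_obs)` under random relabeling of the group
#' labels. When the number of distinct label assignments is small
#' (<= `exhaustive_limit`) the null is enumerated exactly and the plain
#' proportion returned; otherwise `n_perm` random permutations are drawn
#' and the bias-safe estimator `(1 + #{H_perm >= H_obs}) / (1 + n_perm)`
#' is used, so the p-value never reaches 0.
#'
#' @inheritParams kw_statistic
#' @param n_perm number of label permutations (default 10000).
#' @param seed optional integer seed for the permutation draw.
#' @param exhaustive_limit switch to exact enumeration when the count of
#'   distinct assignments is at most this (default 200).
#' @return list with h (observed), pvalue, exact (logical), n_perm used.
#' @export
kw_permutation_p <- function(values, groups, n_perm = 10000, seed = NULL,
                             exhaustive_limit = 200) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  N <- length(values)
  r <- rank(values)
  tie_t <- table(values)
  tie_c <- 1 - sum(tie_t^3 - tie_t) / (N^3 - N)
  n_g <- as.vector(table(groups))
  h_obs <- .kw_h_from_ranksums(tapply(r, groups, sum), n_g, N, tie_c)

  n_assign <- .n_assignments(n_g)
  if (n_assign <= exhaustive_limit) {
    h_all <- .kw_exhaustive_h(r, n_g, N, tie_c)
    p <- mean(h_all >= h_obs - 1e-12)
    return(list(h = h_obs, pvalue = p, exact = TRUE,
                n_perm = length(h_all)))
  }
  if (!is.null(seed)) set.seed(seed)
  ## permute ranks rather than labels; group sums via indicator product
  G <- outer(groups, levels(groups), "==") * 1  # N x k
  P <- vapply(seq_len(n_perm), function(i) r[sample.int(N)],
              numeric(N))                       # N x n_perm
  RS <- crossprod(G, P)                         # k x n_perm group rank sums
  h_perm <- 12 / (N * (N + 1)) * colSums(RS^2 / n_g) - 3 * (N + 1)
  h_perm <- if (tie_c <= 0) rep(0, n_perm) else h_perm / tie_c
  p <- (1 + sum(h_perm >= h_obs - 1e-12)) / (1 + n_perm)
  list(h = h_obs, pvalue = p, exact = FALSE, n_perm = n_perm)
}

#' Test one pan-gene for differential diel regulation
#'
#' Computes each inbred's diel range, tests association with promoter
#' haplotype by Kruskal-Wallis permutation, and applies the three
#' candidacy rules: KW permutation p below `kw_alpha`, at least
#' `min_cycling` inbreds with a significant rhythmicity test (p below
#' `cycling_alpha`), and at least `min_expressed` inbreds with baseline
#' abundance above `expr_floor`. Baseline abundance is the mean
#' normalized value across the time course.
#'
#' @param expr long-format expression rows for this pan-gene (columns
#'   genotype_id, time_h, norm_value).
#' @param haps data.frame with columns genotype_id, haplotype_id for
#'   this pan-gene.
#' @param rhythm data.frame with columns genotype_id, pvalue (per-inbred
#'   rhythmicity test for this pan-gene).
#' @param min_cycling,cycling_alpha,min_expressed,expr_floor,kw_alpha
#'   candidacy thresholds; defaults are the pipeline operating values
#'   (see [diel_defaults()]).
#' @param n_perm,seed passed to [kw_permutation_p()].
#' @return one-row data.frame: kw_H, perm_pvalue, n_cycling_inbreds,
#'   n_expressed_inbreds, n_haplotypes, is_candidate.
#' @export
identify_ddr <- function(expr, haps, rhythm,
                         min_cycling = 6, cycling_alpha = 0.01,
                         min_expressed = 6, expr_floor = 50,
                         kw_alpha = 0.05, n_perm = 10000, seed = NULL) {
  geno <- unique(expr$genotype_id)
  ranges <- vapply(geno, function(g) {
    i <- expr$genotype_id == g
    diel_range(expr$time_h[i], expr$norm_value[i])
  }, numeric(1))
  baseline <- vapply(geno, function(g) {
    mean(expr$norm_value[expr$genotype_id == g])
  }, numeric(1))
  n_expressed <- sum(baseline > expr_floor)
  pv <- rhythm$pvalue[match(geno, rhythm$genotype_id)]
  n_cycling <- sum(pv < cycling_alpha, na.rm = TRUE)

  hap <- haps$haplotype_id[match(geno, haps$genotype_id)]
  keep <- !is.na(hap)
  res <- data.frame(kw_H = NA_real_, perm_pvalue = NA_real_,
                    n_cycling_inbreds = n_cycling,
                    n_expressed_inbreds = n_expressed,
                    n_haplotypes = length(unique(hap[keep])),
                    is_candidate = FALSE)
  if (res$n_haplotypes < 2) return(res)
  kw <- kw_permutation_p(ranges[keep], hap[keep], n_perm = n_perm,
                         seed = seed)
  res$kw_H <- kw$h
  res$perm_pvalue <- kw$pvalue
  res$is_candidate <- kw$pvalue < kw_alpha &&
    n_cycling >= min_cycling && n_expressed >= min_expressed
  res
}

#' DDR scan over all pan-genes
#'
#' Applies [identify_ddr()] to every pan-gene of a long-format
#' expression table. Per-gene permutation seeds are derived from `seed`
#' so the scan is reproducible and genes are independent.
#'
#' @param expr expression long table (gene_id treated as pangene_id).
#' @param haplotypes haplotype table (pangene_id, genotype_id,
#'   haplotype_id).
#' @param rhythm output of [rhythm_scan()].
#' @param ... thresholds passed to [identify_ddr()].
#' @param n_perm,seed permutation settings.
#' @return data.frame with one row per pan-gene, columns as
#'   [identify_ddr()] plus pangene_id.
#' @export
ddr_scan <- function(expr, haplotypes, rhythm, n_perm = 10000,
                     seed = NULL, ...) {
  genes <- unique(expr$gene_id)
  if (!is.null(seed)) {
    set.seed(seed)
    gene_seeds <- sample.int(.Machine$integer.max, length(genes))
  } else {
    gene_seeds <- rep(list(NULL), length(genes))
  }
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    r <- identify_ddr(
      expr[expr$gene_id == g, ],
      haplotypes[haplotypes$pangene_id == g, ],
      rhythm[rhythm$gene_id == g, ],
      n_perm = n_perm, seed = gene_seeds[[i]], ...
    )
    cbind(pangene_id = g, r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confirm a DDR gene in an independent design
#'
#' Groups the genotypes of a replicated growth-chamber time course by
#' promoter haplotype and tests for amplitude differences with
#' [lr_diff_amplitude()]. One haplotype (or no expression) cannot be
#' tested; two haplotypes give a single test; three or more give all
#' pairwise tests with the smallest p-value kept (no multiplicity
#' correction).
#'
#' @param expr long-format chamber expression rows for this gene
#'   (columns genotype_id, time_h, norm_value).
#' @param haps data.frame with columns genotype_id, haplotype_id.
#' @param alpha significance threshold on the (minimum) amplitude
#'   difference p-value (default 0.01).
#' @param period fixed period in hours (default 24).
#' @return list with status ("tested" or "untested"), pvalue,
#'   significant, n_haplotypes.
#' @export
confirm_ddr <- function(expr, haps, alpha = 0.01, period = 24) {
  if (is.null(expr) || nrow(expr) == 0) {
    return(list(status = "untested", pvalue = NA_real_,
                significant = NA, n_haplotypes = 0L))
  }
  geno <- intersect(unique(expr$genotype_id), haps$genotype_id)
  hap <- haps$haplotype_id[match(geno, haps$genotype_id)]
  haps_u <- unique(hap)
  if (length(haps_u) < 2) {
    return(list(status = "untested", pvalue = NA_real_,
                significant = NA, n_haplotypes = length(haps_u)))
  }
  series_of <- function(h) {
    g <- geno[hap == h]
    i <- expr$genotype_id %in% g
    list(times = expr$time_h[i], values = expr$norm_value[i])
  }
  pairs <- combn(haps_u, 2)
  pv <- apply(pairs, 2, function(pr) {
    lr_diff_amplitude(series_of(pr[1]), series_of(pr[2]),
                      period = period)$pvalue
  })
  p <- min(pv)
  list(status = "tested", pvalue = p, significant = p < alpha,
       n_haplotypes = length(haps_u))
}
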