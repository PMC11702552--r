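mk_genes <- function(n, spacing = 10000, len = 2000, chrom = "chr1") {
  gene_table(sprintf("g%02d", seq_len(n)), chrom,
             seq(0, by = spacing, length.out = n),
             seq(0, by = spacing, length.out = n) + len,
             rep("+", n))
}

test_that("gene windows take the minimum SNP p-value, half-open", {
  genes <- mk_genes(2)
  snps <- data.frame(
    snp_id = sprintf("s%d", 1:5), chrom = "chr1",
    pos = c(500, 1500, 2999, 3000, 9000),
    maf = 0.2, pvalue = c(0.3, 0.001, 0.8, 1e-9, 0.5))
  mp <- gene_min_gwas_p(genes, snps, flank = 1000)
  # gene 1 spans [0,2000): window [-1000, 3000); pos 3000 excluded
  expect_equal(unname(mp["g01"]), 0.001)
  # gene 2 spans [10000,12000): window [9000, 13000); pos 9000 included
  expect_equal(unname(mp["g02"]), 0.5)
  # no SNPs in window -> missing
  empty <- gene_min_gwas_p(mk_genes(1, chrom = "chr9"), snps)
  expect_true(is.na(empty))
})

test_that("GWAS enrichment agrees with exhaustive enumeration on a tiny
           instance", {
  genes <- mk_genes(8)
  set.seed(10)
  snps <- data.frame(snp_id = sprintf("s%d", 1:8), chrom = "chr1",
                     pos = genes$gene_start + 100, maf = 0.2,
                     pvalue = c(1e-6, 1e-5, 0.2, 0.4, 0.6, 0.8, 0.9, 0.95))
  cand <- c("g01", "g02", "g03")
  null_ids <- c("g04", "g05", "g06", "g07", "g08")
  r <- gwas_enrichment(cand, null_ids, genes, snps, n_samples = 999,
                       seed = 1)
  expect_true(r$exact)  # C(5,3) = 10 <= exhaustive limit
  # manual enumeration oracle with the +1/+1 estimator
  minp <- gene_min_gwas_p(genes, snps)
  combos <- combn(null_ids, 3, function(ids) mean(minp[ids]))
  expect_equal(length(r$null_stats), 10)
  p_manual <- (1 + sum(combos <= mean(minp[cand]))) / 11
  expect_equal(r$pvalue, p_manual)
  # candidates hold the extreme p-values: no null draw beats them
  expect_equal(r$pvalue, 1 / 11)
  expect_error(gwas_enrichment(cand, c("g04", "g05"), genes, snps),
               "smaller")
})

test_that("GWAS enrichment p-values are near-uniform under the null", {
  set.seed(77)
  genes <- mk_genes(40)
  snps <- data.frame(snp_id = sprintf("s%d", 1:40), chrom = "chr1",
                     pos = genes$gene_start + 50, maf = 0.2,
                     pvalue = runif(40))
  ps <- vapply(1:60, function(i) {
    cand <- sample(genes$gene_id, 6)
    gwas_enrichment(cand, genes$gene_id, genes, snps, n_samples = 200,
                    seed = i)$pvalue
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("adaptation overlap enrichment handles degenerate and extreme
           cases", {
  genes <- mk_genes(6)
  cand <- c("g01", "g02")
  null_ids <- genes$gene_id
  none <- data.frame(snp_id = character(), chrom = character(),
                     pos = integer())
  r0 <- adaptation_overlap_enrichment(cand, none, null_ids, genes,
                                      n_samples = 100, seed = 1)
  expect_equal(r0$observed_stat, 0)
  expect_equal(r0$pvalue, 1)

  # all adaptation SNPs inside candidate windows, none elsewhere:
  # enumeration over C(6,2) = 15 null draws; only {g01, g02} ties the
  # observed overlap of 2
  inside <- data.frame(snp_id = c("a1", "a2"), chrom = "chr1",
                       pos = c(100, 10100))
  r1 <- adaptation_overlap_enrichment(cand, inside, null_ids, genes,
                                      n_samples = 100, seed = 1)
  expect_true(r1$exact)
  expect_equal(r1$observed_stat, 2)
  expect_equal(r1$pvalue, 2 / 16)
  # with candidates excluded from the null set no draw can match
  r2 <- adaptation_overlap_enrichment(cand, inside, null_ids[3:6],
                                      genes, n_samples = 100, seed = 1)
  expect_equal(r2$pvalue, 1 / (choose(4, 2) + 1))
})

test_that("Fisher's combined test matches closed forms", {
  expect_equal(fisher_combined(0.5), 0.5)
  expect_equal(fisher_combined(c(1, 1, 1)), 1)
  # df = 4 has a closed-form upper tail independent of pchisq
  x <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(x, 11.98293, tolerance = 1e-5)
  expect_equal(fisher_combined(c(0.05, 0.05)), chisq4_upper(x),
               tolerance = 1e-12)
  expect_error(fisher_combined(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Weir-Cockerham Fst matches hand-computed components", {
  # fixed difference, 30 diploids per population
  fd <- weir_cockerham_fst(rep(0, 30), rep(2, 30))
  expect_equal(fd$fst, 1)

  # hand-worked case: pop1 {0/0, 0/1}, pop2 {1/1, 0/1}
  # p1 = .25, p2 = .75, h = .5 both; nbar = nc = 2, pbar = .5,
  # s2 = .125, hbar = .5 -> a = 1/16, b = 0, c = 1/4, fst = 0.2
  h <- weir_cockerham_fst(c(0, 1), c(2, 1))
  expect_equal(h$a, 0.0625, tolerance = 1e-12)
  expect_equal(h$b, 0, tolerance = 1e-12)
  expect_equal(h$c, 0.25, tolerance = 1e-12)
  expect_equal(h$fst, 0.2, tolerance = 1e-12)

  # identical genotype counts: no differentiation, estimate <= 0
  same <- weir_cockerham_fst(c(0, 1, 1, 2), c(0, 1, 1, 2))
  expect_lte(same$fst, 0)

  # monomorphic across both populations -> missing
  mono <- weir_cockerham_fst(rep(0, 10), rep(0, 10))
  expect_true(is.na(mono$fst))

  # missing genotypes are dropped; too few leaves NA
  expect_true(is.na(weir_cockerham_fst(c(0, NA), c(1, 1))$fst))
})

test_that("top-k SNP selection ranks by Fst with genomic tie-breaks", {
  snps <- data.frame(snp_id = sprintf("s%d", 1:5),
                     chrom = c("chr2", "chr1", "chr1", "chr1", "chr2"),
                     pos = c(50, 10, 99, 5, 700))
  fst <- c(0.9, 0.5, 0.5, 0.1, NA)
  all5 <- top_k_snps(snps, fst, k = 10)
  expect_equal(nrow(all5), 4)  # NA dropped
  expect_equal(all5$snp_id[1], "s1")
  top3 <- top_k_snps(snps, fst, k = 3)
  # tie at 0.5 broken by genomic order: chr1:10 before chr1:99
  expect_equal(top3$snp_id, c("s1", "s2", "s3"))
})

test_that("night-day response subtracts matched individuals", {
  expect_equal(night_day_response(10, 4), 6)
  expect_equal(night_day_response(c(i1 = 5, i2 = 7), c(i2 = 7, i1 = 2)),
               c(i1 = 3, i2 = 0))
  out <- night_day_response(c(i1 = 5), c(i2 = 2))
  expect_true(is.na(out["i1"]))
})

test_that("cis-eQTL scan matches the closed-form OLS t-test", {
  set.seed(20)
  n <- 40
  gene <- mk_genes(1)
  dos <- rbinom(n, 2, 0.3)
  resp <- 0.5 * dos + rnorm(n)
  names(resp) <- sprintf("i%02d", 1:n)
  snps <- data.frame(snp_id = "s1", chrom = "chr1", pos = 2500,
                     maf = 0.3, pvalue = NA)
  snps[names(resp)] <- as.list(dos)
  r <- cis_eqtl_scan(resp, snps, gene[1, ], window = 5000)
  ft <- summary(lm(resp ~ dos))$coefficients
  expect_equal(r$beta, unname(ft[2, 1]), tolerance = 1e-9)
  expect_equal(r$pvalue, unname(ft[2, 4]), tolerance = 1e-9)

  # perfect signal
  resp2 <- setNames(2 * dos, names(resp))
  r2 <- cis_eqtl_scan(resp2, snps, gene[1, ], window = 5000)
  expect_lt(r2$pvalue, 1e-10)

  # monomorphic SNP is skipped with an NA row
  snps_mono <- snps
  snps_mono[names(resp)] <- as.list(rep(1, n))
  r3 <- cis_eqtl_scan(resp, snps_mono, gene[1, ], window = 5000)
  expect_true(is.na(r3$pvalue))

  expect_error(cis_eqtl_scan(resp[1:5], snps, gene[1, ]), ">= 10")
})

test_that("SNP-to-gene distances and matched-overlap extremes behave", {
  genes <- mk_genes(2)
  snps <- data.frame(
    snp_id = sprintf("s%d", 1:6), chrom = "chr1",
    pos = c(100, 2100, 5000, 9999, 10500, 13000),
    maf = rep(c(0.1, 0.4), 3),
    pvalue = c(1e-8, 0.5, 0.5, 0.5, 1e-8, 0.5))
  # last covered base of gene 1 is 1999 (half-open end), so the SNP at
  # 5000 is 3001 bp away
  d <- snp_gene_distance(snps, genes)
  expect_equal(d, c(0, 101, 3001, 1, 0, 1001))

  # both eQTL SNPs are hits; draws come from strata where the only
  # other members are non-hits -> minimal p
  r <- matched_overlap_test(c("s1", "s5"), snps, genes, n_draws = 50,
                            seed = 2)
  expect_equal(r$observed_stat, 2)
  expect_gte(r$pvalue, 1 / 51)

  # no hits anywhere: p = 1
  snps2 <- snps; snps2$pvalue <- 0.5
  r2 <- matched_overlap_test(c("s1", "s5"), snps2, genes, n_draws = 50,
                             seed = 2)
  expect_equal(r2$observed_stat, 0)
  expect_equal(r2$pvalue, 1)
  expect_error(matched_overlap_test("nope", snps, genes), "present")
})

test_that("null gene sets partition by cycling evidence", {
  rhythm <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 24),
    genotype_id = rep(sprintf("i%02d", 1:24), 3),
    M = rep(c(100, 3, 50), each = 24),
    pvalue = c(rep(1e-5, 24),            # g1 cycles everywhere
               rep(0.5, 24),             # g2 never
               c(1e-5, 1e-5, rep(0.5, 22))))  # g3 in two inbreds
  ns <- null_gene_sets(rhythm)
  expect_setequal(ns$all_genes, c("g1", "g2", "g3"))
  expect_setequal(ns$transcribed, c("g1", "g3"))
  expect_setequal(ns$cycling_ge2, c("g1", "g3"))
  expect_setequal(ns$cycling_ge22, "g1")
})
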