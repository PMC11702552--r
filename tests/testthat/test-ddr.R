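field_grid <- seq(6, 28, by = 2)

test_that("diel range is max minus min with replicates averaged first", {
  expect_equal(diel_range(field_grid, rep(4, 12)), 0)
  y <- 5 + 2 * sin(2 * pi * field_grid / 24)
  # the field grid contains the exact extrema (t = 6 and t = 18)
  expect_equal(diel_range(field_grid, y), 4)
  expect_equal(diel_range(3, 7.5), 0)
  # replicates at one timepoint are averaged before the range
  expect_equal(diel_range(c(1, 1, 2), c(0, 10, 4)), 1)
  expect_error(diel_range(numeric(0), numeric(0)), "empty")
})

test_that("KW statistic matches kruskal.test including ties", {
  expect_equal(kw_statistic(1:6, rep(c("A", "B"), each = 3)),
               unname(kruskal.test(1:6, factor(rep(c("A", "B"),
                                                   each = 3)))$statistic))
  set.seed(4)
  for (i in 1:15) {
    v <- sample(c(rnorm(10), rep(0.5, 4)))  # include ties
    g <- sample(c("a", "b", "c"), 14, replace = TRUE)
    if (length(unique(g)) < 2) next
    expect_equal(kw_statistic(v, g),
                 unname(kruskal.test(v, factor(g))$statistic),
                 tolerance = 1e-12)
  }
  expect_equal(kw_statistic(rep(1, 6), rep(c("A", "B"), 3)), 0)
  expect_error(kw_statistic(1:5, rep("A", 5)), "2 groups")
})

test_that("KW statistic is invariant under joint reordering", {
  set.seed(8)
  v <- rnorm(12)
  g <- rep(c("x", "y", "z"), 4)
  h0 <- kw_statistic(v, g)
  p <- sample(12)
  expect_equal(kw_statistic(v[p], g[p]), h0, tolerance = 1e-12)
})

test_that("KW permutation p is exact on small instances", {
  # C(6,3) = 20 assignments; 2 of them reach the observed H
  r <- kw_permutation_p(1:6, rep(c("A", "B"), each = 3))
  expect_true(r$exact)
  expect_equal(r$pvalue, 0.1)
  expect_equal(r$pvalue, exhaustive_kw_p_two_groups(1:6, 3))

  # all-tied data: H = 0, every assignment ties, p = 1
  r0 <- kw_permutation_p(rep(2, 6), rep(c("A", "B"), each = 3))
  expect_equal(r0$h, 0)
  expect_equal(r0$pvalue, 1)
})

test_that("sampled KW permutation p has the +1/+1 floor and fixed seed", {
  set.seed(2)
  v <- c(rnorm(12), rnorm(12) + 5)
  g <- rep(c("a", "b"), each = 12)  # C(24,12) >> exhaustive limit
  r1 <- kw_permutation_p(v, g, n_perm = 500, seed = 31)
  r2 <- kw_permutation_p(v, g, n_perm = 500, seed = 31)
  expect_false(r1$exact)
  expect_identical(r1$pvalue, r2$pvalue)
  expect_gte(r1$pvalue, 1 / 501)
  expect_equal(r1$pvalue, 1 / 501)  # total separation
})

test_that("DDR candidacy applies all three filter rules", {
  # build a pan-gene cycling in only 5 inbreds with a strong haplotype
  # effect: must not be a candidate
  set.seed(6)
  geno <- sprintf("g%02d", 1:12)
  hap <- rep(c("h1", "h2"), each = 6)
  mk_series <- function(g, A) {
    data.frame(gene_id = "pg", genotype_id = g, replicate = 1L,
               time_h = field_grid,
               count = NA,
               norm_value = 100 + A * sin(2 * pi * field_grid / 24) +
                 rnorm(12, 0, 0.3))
  }
  amp <- c(rep(3, 5), rep(0, 7))  # only 5 cycling inbreds
  expr <- do.call(rbind, Map(mk_series, geno, amp))
  haps <- data.frame(genotype_id = geno, haplotype_id = hap)
  rhythm <- data.frame(genotype_id = geno,
                       pvalue = c(rep(1e-6, 5), runif(7, 0.3, 1)))
  res <- identify_ddr(expr, haps, rhythm, n_perm = 500, seed = 1)
  expect_equal(res$n_cycling_inbreds, 5)
  expect_false(res$is_candidate)

  # same gene with 6 cycling inbreds and clear haplotype segregation
  amp6 <- c(rep(3, 6), rep(0, 6))
  expr6 <- do.call(rbind, Map(mk_series, geno, amp6))
  rhythm6 <- data.frame(genotype_id = geno,
                        pvalue = c(rep(1e-6, 6), runif(6, 0.3, 1)))
  res6 <- identify_ddr(expr6, haps, rhythm6, n_perm = 500, seed = 1)
  expect_true(res6$is_candidate)
  expect_lt(res6$perm_pvalue, 0.05)

  # single haplotype: no test
  haps1 <- data.frame(genotype_id = geno, haplotype_id = "h1")
  res1 <- identify_ddr(expr6, haps1, rhythm6, n_perm = 100, seed = 1)
  expect_true(is.na(res1$perm_pvalue))
  expect_false(res1$is_candidate)
})

test_that("identify_ddr is invariant to inbred order and haplotype names", {
  st <- small_study(seed = 12, n_pangenes = 12, n_inbreds = 12)
  g <- st$genes$gene_id[st$genes$is_ddr][1]
  expr <- st$expression_field[st$expression_field$gene_id == g, ]
  haps <- st$haplotypes[st$haplotypes$pangene_id == g, ]
  rhythm <- rhythm_scan(expr)
  base <- identify_ddr(expr, haps, rhythm, n_perm = 300, seed = 5)

  perm <- sample(nrow(expr))
  res_shuf <- identify_ddr(expr[perm, ], haps, rhythm,
                           n_perm = 300, seed = 5)
  expect_equal(res_shuf$kw_H, base$kw_H, tolerance = 1e-12)

  haps2 <- haps
  haps2$haplotype_id <- paste0("renamed_", haps2$haplotype_id)
  res_ren <- identify_ddr(expr, haps2, rhythm, n_perm = 300, seed = 5)
  expect_equal(res_ren$kw_H, base$kw_H, tolerance = 1e-12)
  expect_equal(res_ren$perm_pvalue, base$perm_pvalue)
})

test_that("chamber confirmation follows the 1/2/3-haplotype rule", {
  chamber_grid <- seq(0, 30, 3)
  mk <- function(g, A, reps = 2) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      data.frame(gene_id = "pg", genotype_id = g, replicate = r,
                 time_h = chamber_grid, count = NA,
                 norm_value = 50 + A * sin(2 * pi * chamber_grid / 24) +
                   rnorm(11, 0, 0.3))
    }))
  }
  set.seed(14)
  # all genotypes share one haplotype: untested
  haps_same <- data.frame(genotype_id = c("a", "b", "c"),
                          haplotype_id = "h1")
  expr <- rbind(mk("a", 0), mk("b", 0), mk("c", 0))
  expect_equal(confirm_ddr(expr, haps_same)$status, "untested")
  expect_equal(confirm_ddr(expr[0, ], haps_same)$status, "untested")

  # two haplotypes, no amplitude difference: tested, not significant
  haps2 <- data.frame(genotype_id = c("a", "b", "c"),
                      haplotype_id = c("h1", "h1", "h2"))
  r2 <- confirm_ddr(expr, haps2)
  expect_equal(r2$status, "tested")
  expect_false(r2$significant)

  # three haplotypes, amplitudes 0/0/3: min pairwise p significant
  haps3 <- data.frame(genotype_id = c("a", "b", "c"),
                      haplotype_id = c("h1", "h2", "h3"))
  hits <- 0
  for (i in 1:10) {
    expr3 <- rbind(mk("a", 0), mk("b", 0), mk("c", 3))
    hits <- hits + (confirm_ddr(expr3, haps3)$pvalue < 0.01)
  }
  expect_gte(hits, 9)
})
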