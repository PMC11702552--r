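test_that("simulation is fully deterministic under a seed", {
  a <- simulate_study(sim_config(n_pangenes = 15, n_inbreds = 6,
                                 seed = 99))
  b <- simulate_study(sim_config(n_pangenes = 15, n_inbreds = 6,
                                 seed = 99))
  expect_identical(a$expression_field, b$expression_field)
  expect_identical(a$promoters$sequences, b$promoters$sequences)
  expect_identical(a$snps, b$snps)
  expect_identical(a$haplotypes, b$haplotypes)
})

test_that("pangenome respects core fraction and exact DDR counts", {
  pan <- simulate_pangenome(sim_config(n_pangenes = 60, n_inbreds = 10,
                                       core_fraction = 1, frac_ddr = 0.1),
                            seed = 3)
  counts <- table(pan$members$pangene_id)
  expect_true(all(counts == 10))
  expect_equal(sum(pan$genes$is_ddr), 6)
  # DDR genes have >= 2 haplotypes with distinct true amplitudes
  for (g in pan$genes$gene_id[pan$genes$is_ddr]) {
    amp <- pan$truth$hap_amplitude$amplitude[
      pan$truth$hap_amplitude$pangene_id == g]
    expect_gte(length(unique(amp)), 2)
  }
  expect_error(simulate_pangenome(sim_config(n_inbreds = 1)), "n_inbreds")
  expect_error(sim_config(frac_ddr = 1.5), "fractions")
})

test_that("noise-free expression equals the sinusoid exactly", {
  cfg <- sim_config(n_pangenes = 8, n_inbreds = 4, sigma = 0, seed = 21)
  pan <- simulate_pangenome(cfg, seed = 21)
  expr <- simulate_expression(cfg, pan, "field", seed = 22)
  tr <- pan$truth$geno_params
  for (i in sample(nrow(tr), 5)) {
    sel <- expr$gene_id == tr$pangene_id[i] &
      expr$genotype_id == tr$genotype_id[i]
    expected <- pmax(tr$mesor[i] + tr$amplitude[i] *
                       sin(2 * pi * expr$time_h[sel] / 24 + tr$phase[i]), 0)
    expect_equal(expr$norm_value[sel], expected, tolerance = 1e-12)
  }
  # a non-rhythmic gene is constant at its MESOR
  flat <- tr[tr$amplitude == 0, ][1, ]
  sel <- expr$gene_id == flat$pangene_id &
    expr$genotype_id == flat$genotype_id
  expect_equal(expr$norm_value[sel], rep(flat$mesor, 12),
               tolerance = 1e-12)
})

test_that("chamber design replicates the stated sampling schedule", {
  cfg <- sim_config(n_pangenes = 5, n_inbreds = 6, seed = 4)
  pan <- simulate_pangenome(cfg, seed = 4)
  ch <- simulate_expression(cfg, pan, "chamber", seed = 5)
  expect_setequal(unique(ch$genotype_id),
                  sprintf("inb%02d", 1:4))
  one <- ch[ch$gene_id == ch$gene_id[1] & ch$genotype_id == "inb01", ]
  expect_equal(nrow(one), 22)  # 11 timepoints x 2 replicates
  expect_equal(sort(unique(one$time_h)), seq(0, 30, 3))
  fld <- simulate_expression(cfg, pan, "field", seed = 5)
  expect_equal(sort(unique(fld$time_h)), seq(6, 28, 2))
})

test_that("promoters plant the motif only in rhythmic haplotypes", {
  cfg <- sim_config(n_pangenes = 30, n_inbreds = 6, seed = 8)
  pan <- simulate_pangenome(cfg, seed = 8)
  prom <- simulate_promoters(cfg, pan, seed = 9)
  expect_true(all(nchar(prom$hap_sequences) == 1500))
  # recorded positions contain the motif exactly
  mp <- prom$motif_positions
  expect_gt(nrow(mp), 0)
  for (i in sample(nrow(mp), min(10, nrow(mp)))) {
    s <- prom$hap_sequences[paste(mp$pangene_id[i], mp$haplotype_id[i],
                                  sep = "|")]
    expect_equal(unname(substr(s, mp$pos[i] + 1, mp$pos[i] + 8)),
                 "AAATATCT")
  }
  # motif-bearing haplotypes are exactly those with positive amplitude
  ha <- pan$truth$hap_amplitude
  planted <- unique(paste(mp$pangene_id, mp$haplotype_id))
  expect_setequal(planted,
                  paste(ha$pangene_id, ha$haplotype_id)[ha$amplitude > 0])

  # no rhythmic genes -> nothing planted
  cfg0 <- sim_config(n_pangenes = 20, n_inbreds = 6, frac_rhythmic = 0,
                     frac_ddr = 0)
  pan0 <- simulate_pangenome(cfg0, seed = 10)
  prom0 <- simulate_promoters(cfg0, pan0, seed = 11)
  expect_equal(nrow(prom0$motif_positions), 0)

  expect_error(
    simulate_promoters(sim_config(promoter_len = 6L,
                                  motif = "AAATATCT"), pan0),
    "longer")
})

test_that("background base composition matches the configured GC", {
  cfg <- sim_config(n_pangenes = 40, n_inbreds = 4, frac_rhythmic = 0,
                    frac_ddr = 0, gc = 0.5)
  pan <- simulate_pangenome(cfg, seed = 13)
  prom <- simulate_promoters(cfg, pan, seed = 14)
  bases <- strsplit(paste(prom$hap_sequences, collapse = ""), "")[[1]]
  gc_obs <- mean(bases %in% c("G", "C"))
  n <- length(bases)
  expect_lt(abs(gc_obs - 0.5), 4 * sqrt(0.25 / n) + 1e-3)
})

test_that("SNP tables respect MAF bounds, sorting and HWE genotypes", {
  cfg <- sim_config(n_pangenes = 30, n_inbreds = 6, n_snps = 1500,
                    n_individuals = 500)
  pan <- simulate_pangenome(cfg, seed = 17)
  sn <- simulate_snps(cfg, pan, seed = 18)
  s <- sn$snps
  expect_true(all(s$maf > 0 & s$maf <= 0.5))
  expect_true(all(s$pvalue > 0 & s$pvalue <= 1))
  for (ch in unique(s$chrom)) {
    expect_false(is.unsorted(s$pos[s$chrom == ch]))
  }
  # Hardy-Weinberg check on a handful of SNPs via chi-square
  geno_cols <- grep("^ind", names(s))
  set.seed(1)
  bad <- 0
  picks <- sample(nrow(s), 20)
  for (i in picks) {
    g <- as.numeric(s[i, geno_cols])
    p <- s$maf[i]
    expected <- 500 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(g + 1, 3)
    chi <- sum((obs - expected)^2 / expected)
    bad <- bad + (pchisq(chi, df = 2, lower.tail = FALSE) < 0.001)
  }
  expect_lte(bad, 2)
})

test_that("GWAS p-values are spiked near DDR genes and flat elsewhere", {
  cfg <- sim_config(n_pangenes = 60, n_inbreds = 8, n_snps = 4000)
  pan <- simulate_pangenome(cfg, seed = 23)
  sp <- simulate_snps(cfg, pan, seed = 24)
  expect_lt(median(sp$snps$pvalue[sp$near_ddr]), 0.1)
  bg <- sp$snps$pvalue[!sp$near_ddr]
  expect_gt(mean(bg), 0.45); expect_lt(mean(bg), 0.55)

  cfg_off <- sim_config(n_pangenes = 60, n_inbreds = 8, n_snps = 4000,
                        gwas_spike = FALSE)
  sp0 <- simulate_snps(cfg_off, pan, seed = 24)
  spiked <- sp0$snps$pvalue[sp0$near_ddr]
  expect_gt(mean(spiked), 0.4)
})
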