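## Synthetic study generator with a full ground-truth ledger. The
## simulated design mirrors the study layout: 24 inbreds sampled every
## 2 h over 24 h in the field (hours 6..28), and 4 genotypes sampled
## every 3 h over 30 h with 2 replicates in the growth chamber. Diel
## expression is a fixed-period sinusoid plus Gaussian noise, clipped
## at zero; DDR genes carry haplotype-dependent amplitudes; rhythmic
## promoter haplotypes carry planted copies of a clock motif; SNP
## association p-values are spiked near DDR genes.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_study()] and the
#' individual generators. Defaults encode the study conditions: 24
#' inbreds on the 12-point field grid (hours 6, 8, ..., 28), an
#' 11-point chamber grid (hours 0, 3, ..., 30) with 2 replicates,
#' period 24 h, DDR haplotype amplitudes 0 vs 3 with noise sd 0.3, and
#' the Evening Element AAATATCT planted in rhythmic promoters.
#'
#' @param ... overrides of any default field; unknown names error.
#' @return list of class "sim_config".
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_inbreds = 24L, n_pangenes = 200L,
    core_fraction = 0.9, frac_rhythmic = 0.3, frac_ddr = 0.1,
    timepoints_field = seq(6, 28, by = 2),
    timepoints_chamber = seq(0, 30, by = 3),
    chamber_reps = 2L, n_chamber_genotypes = 4L,
    period = 24,
    ddr_amplitudes = c(0, 3), ddr_min_class = 6L,
    amp_meanlog = log(2), amp_sdlog = 0.4,
    mesor_meanlog = log(100), mesor_sdlog = 0.4,
    mesor_geno_sdlog = 0.1,
    sigma = 0.3,
    motif = "AAATATCT", promoter_len = 1500L, gc = 0.45,
    n_snps = 4000L, n_chrom = 5L,
    gene_spacing = 8000L, gene_len = 3000L,
    gwas_spike = TRUE, spike_beta_a = 0.1,
    p_adapt = 0.3, p_adapt_bg = 0.02,
    n_individuals = 0L,
    seed = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  frac <- c(cfg$core_fraction, cfg$frac_rhythmic, cfg$frac_ddr)
  if (any(frac < 0 | frac > 1)) stop("fractions must be in [0, 1]")
  if (cfg$n_inbreds < 2) stop("n_inbreds must be >= 2")
  if (cfg$n_pangenes < 1) stop("n_pangenes must be >= 1")
  if (cfg$sigma < 0) stop("sigma must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a pangenome with promoter haplotypes and ground truth
#'
#' Generates pan-genes (core at rate `core_fraction`, else present in a
#' random subset of inbreds), reference gene coordinates on
#' `n_chrom` chromosomes, 1-4 promoter haplotypes per pan-gene
#' distributed over inbreds, and the truth ledger: per-haplotype
#' amplitudes (DDR genes alternate the two `ddr_amplitudes` classes,
#' each class carried by at least `ddr_min_class` inbreds), shared
#' per-gene phase, and per-(gene, inbred) MESOR. Exactly
#' `round(frac_ddr * n_pangenes)` genes are DDR and
#' `round(frac_rhythmic * n_pangenes)` are rhythmic (DDR genes counted
#' among them).
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed (omit inside [simulate_study()],
#'   which seeds once globally).
#' @return list: inbreds, genes (gene table with pangene flags),
#'   members, haplotypes, truth (hap_amplitude, gene_params,
#'   geno_params data.frames).
#' @export
simulate_pangenome <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_inbreds
  if (n < 2) stop("n_inbreds must be >= 2")
  inbreds <- sprintf("inb%02d", seq_len(n))
  np <- cfg$n_pangenes
  pg <- sprintf("pg%04d", seq_len(np))

  n_ddr <- round(cfg$frac_ddr * np)
  n_rhy <- max(round(cfg$frac_rhythmic * np), n_ddr)
  ddr_ids <- sample(pg, n_ddr)
  rhy_ids <- c(ddr_ids, sample(setdiff(pg, ddr_ids), n_rhy - n_ddr))

  is_core <- runif(np) < cfg$core_fraction
  members <- lapply(seq_len(np), function(i) {
    who <- if (is_core[i]) inbreds else {
      k <- sample(2:max(2, n - 1), 1)
      sort(sample(inbreds, k))
    }
    data.frame(pangene_id = pg[i], genotype_id = who,
               gene_id = paste0(pg[i], "_", who),
               stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, members)

  ## reference coordinates, round-robin over chromosomes
  chrom <- sprintf("chr%d", ((seq_len(np) - 1) %% cfg$n_chrom) + 1)
  idx_on_chrom <- ave(seq_len(np), chrom, FUN = seq_along)
  start <- 2000L + (idx_on_chrom - 1L) * cfg$gene_spacing
  end <- start + cfg$gene_len
  strand <- sample(c("+", "-"), np, replace = TRUE)
  genes <- gene_table(pg, chrom, start, end, strand)
  genes$is_ddr <- pg %in% ddr_ids
  genes$is_rhythmic <- pg %in% rhy_ids

  hap_rows <- list(); amp_rows <- list()
  for (i in seq_len(np)) {
    mem <- members$genotype_id[members$pangene_id == pg[i]]
    nm <- length(mem)
    ddr <- pg[i] %in% ddr_ids
    k <- if (ddr) sample(2:4, 1) else sample(1:4, 1)
    k <- min(k, nm)
    if (ddr) k <- max(k, 2L)
    ## haplotype class (amplitude group) alternates over haplotype index
    cls <- ((seq_len(k) - 1L) %% 2L) + 1L
    assign_ok <- function(h) {
      if (!ddr) return(TRUE)
      cnt <- tabulate(cls[h], nbins = 2)
      all(cnt >= min(cfg$ddr_min_class, floor(nm / 2)))
    }
    h <- NULL
    for (try in 1:100) {
      w <- rgamma(k, shape = 2)
      h_try <- sample.int(k, nm, replace = TRUE, prob = w / sum(w))
      if (length(unique(h_try)) == k && assign_ok(h_try)) {
        h <- h_try; break
      }
    }
    if (is.null(h)) {  # deterministic fallback: balanced assignment
      h <- rep(seq_len(k), length.out = nm)[sample.int(nm)]
    }
    if (pg[i] %in% rhy_ids && !ddr) {
      shared_a <- rlnorm(1, cfg$amp_meanlog, cfg$amp_sdlog)
      amps <- rep(shared_a, k)
    } else if (ddr) {
      amps <- cfg$ddr_amplitudes[cls]
    } else {
      amps <- rep(0, k)
    }
    hap_ids <- sprintf("%s_hap%d", pg[i], seq_len(k))
    hap_rows[[i]] <- data.frame(
      pangene_id = pg[i], genotype_id = mem, haplotype_id = hap_ids[h],
      stringsAsFactors = FALSE)
    amp_rows[[i]] <- data.frame(
      pangene_id = pg[i], haplotype_id = hap_ids, amplitude = amps,
      stringsAsFactors = FALSE)
  }
  haplotypes <- do.call(rbind, hap_rows)
  hap_amplitude <- do.call(rbind, amp_rows)

  gene_params <- data.frame(
    pangene_id = pg,
    phase = runif(np, 0, 2 * pi),
    mesor = rlnorm(np, cfg$mesor_meanlog, cfg$mesor_sdlog),
    is_ddr = genes$is_ddr, is_rhythmic = genes$is_rhythmic,
    stringsAsFactors = FALSE)

  geno_params <- merge(members, haplotypes,
                       by = c("pangene_id", "genotype_id"))
  geno_params <- merge(geno_params, hap_amplitude,
                       by = c("pangene_id", "haplotype_id"))
  geno_params <- merge(geno_params,
                       gene_params[c("pangene_id", "phase", "mesor")],
                       by = "pangene_id")
  geno_params$mesor <- geno_params$mesor *
    rlnorm(nrow(geno_params), 0, cfg$mesor_geno_sdlog)
  geno_params <- geno_params[order(geno_params$pangene_id,
                                   geno_params$genotype_id), ]
  rownames(geno_params) <- NULL

  list(inbreds = inbreds, genes = genes, members = members,
       haplotypes = haplotypes,
       truth = list(hap_amplitude = hap_amplitude,
                    gene_params = gene_params,
                    geno_params = geno_params))
}

#' Simulate diel expression for a design
#'
#' Evaluates `y(t) = M + A sin(2 pi t / period + phi) + e` with
#' `e ~ N(0, sigma^2)` and zero-clipping for every (pan-gene, genotype)
#' in the truth ledger, on either the field grid (one series per
#' inbred) or the chamber grid (first `n_chamber_genotypes` inbreds,
#' `chamber_reps` replicates).
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_pangenome()].
#' @param design "field" or "chamber".
#' @param seed optional integer seed.
#' @return expression long data.frame (gene_id = pangene_id, count NA).
#' @export
simulate_expression <- function(cfg, sim, design = c("field", "chamber"),
                                seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  gp <- sim$truth$geno_params
  if (design == "chamber") {
    keep_g <- sim$inbreds[seq_len(min(cfg$n_chamber_genotypes,
                                      length(sim$inbreds)))]
    gp <- gp[gp$genotype_id %in% keep_g, ]
    times <- cfg$timepoints_chamber
    reps <- cfg$chamber_reps
  } else {
    times <- cfg$timepoints_field
    reps <- 1L
  }
  nt <- length(times)
  nrow_out <- nrow(gp) * nt * reps
  w <- 2 * pi / cfg$period
  rep_id <- rep(seq_len(reps), each = nt)
  tt <- rep(times, reps)
  out <- data.frame(
    gene_id = rep(gp$pangene_id, each = nt * reps),
    genotype_id = rep(gp$genotype_id, each = nt * reps),
    replicate = rep(rep_id, nrow(gp)),
    time_h = rep(tt, nrow(gp)),
    count = NA_real_,
    norm_value = NA_real_,
    stringsAsFactors = FALSE)
  mu <- rep(gp$mesor, each = nt * reps) +
    rep(gp$amplitude, each = nt * reps) *
      sin(w * out$time_h + rep(gp$phase, each = nt * reps))
  out$norm_value <- pmax(mu + rnorm(nrow_out, 0, cfg$sigma), 0)
  out
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate promoter sequences with planted motifs
#'
#' One background sequence per (pan-gene, haplotype) at the configured
#' GC content; haplotypes whose true amplitude is positive receive 1-3
#' copies of the planted motif at uniform random non-overlapping
#' positions. Every inbred carrying a haplotype shares its sequence, so
#' promoter sequence and diel amplitude co-vary exactly as the
#' haplotype model prescribes. Planted positions are recorded.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_pangenome()].
#' @param seed optional integer seed.
#' @return list: sequences (named "pangene|genotype"), hap_sequences
#'   (named "pangene|haplotype"), motif_positions data.frame
#'   (pangene_id, haplotype_id, pos — 0-based offset).
#' @export
simulate_promoters <- function(cfg, sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- cfg$promoter_len
  motif <- toupper(cfg$motif)
  mw <- nchar(motif)
  if (mw > L) stop("motif longer than promoter sequence")
  ha <- sim$truth$hap_amplitude
  hap_seqs <- character(nrow(ha))
  pos_rows <- list()
  for (i in seq_len(nrow(ha))) {
    s <- .random_dna(L, cfg$gc)
    if (ha$amplitude[i] > 0) {
      n_copies <- sample(1:3, 1)
      taken <- integer(0)
      placed <- integer(0)
      for (cpy in seq_len(n_copies)) {
        for (try in 1:50) {
          p <- sample.int(L - mw + 1L, 1) - 1L  # 0-based
          if (!any(abs(p - taken) < mw)) {
            substr(s, p + 1L, p + mw) <- motif
            taken <- c(taken, p); placed <- c(placed, p)
            break
          }
        }
      }
      pos_rows[[length(pos_rows) + 1]] <- data.frame(
        pangene_id = ha$pangene_id[i], haplotype_id = ha$haplotype_id[i],
        pos = placed, stringsAsFactors = FALSE)
    }
    hap_seqs[i] <- s
  }
  names(hap_seqs) <- paste(ha$pangene_id, ha$haplotype_id, sep = "|")
  hp <- sim$haplotypes
  seqs <- hap_seqs[paste(hp$pangene_id, hp$haplotype_id, sep = "|")]
  names(seqs) <- paste(hp$pangene_id, hp$genotype_id, sep = "|")
  motif_positions <- if (length(pos_rows)) do.call(rbind, pos_rows) else
    data.frame(pangene_id = character(), haplotype_id = character(),
               pos = integer(), stringsAsFactors = FALSE)
  list(sequences = seqs, hap_sequences = hap_seqs,
       motif_positions = motif_positions)
}

#' Simulate SNPs, GWAS p-values and adaptation candidates
#'
#' SNP positions are uniform along each chromosome; minor allele
#' frequencies are Uniform(0.05, 0.5). Association p-values are
#' Uniform(0, 1) in the background; SNPs within 1000 bp of a DDR gene
#' span are drawn from Beta(`spike_beta_a`, 1) when the spike is
#' enabled. Adaptation candidates are near-DDR SNPs with probability
#' `p_adapt` plus background SNPs at rate `p_adapt_bg`. Optional
#' genotype dosages for `n_individuals` are drawn binomially at the
#' SNP's allele frequency (Hardy-Weinberg).
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_pangenome()].
#' @param seed optional integer seed.
#' @return list: snps (SNP table, plus genotype columns when
#'   `n_individuals > 0`), adaptation_snp_ids, near_ddr (logical).
#' @export
simulate_snps <- function(cfg, sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sim$genes
  chroms <- unique(genes$chrom)
  chrom_len <- vapply(chroms, function(ch) {
    max(genes$gene_end[genes$chrom == ch]) + 2000L
  }, numeric(1))
  per <- table(factor(sample(chroms, cfg$n_snps, replace = TRUE,
                             prob = chrom_len / sum(chrom_len)),
                      levels = chroms))
  rows <- lapply(chroms, function(ch) {
    k <- per[[ch]]
    data.frame(chrom = ch, pos = sort(sample.int(chrom_len[[ch]], k)),
               stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, rows)
  snps$snp_id <- sprintf("snp%05d", seq_len(nrow(snps)))
  snps$maf <- runif(nrow(snps), 0.05, 0.5)

  ddr_genes <- genes[genes$is_ddr, , drop = FALSE]
  near <- rep(FALSE, nrow(snps))
  for (i in seq_len(nrow(ddr_genes))) {
    near <- near | (snps$chrom == ddr_genes$chrom[i] &
                      snps$pos >= ddr_genes$gene_start[i] - 1000 &
                      snps$pos < ddr_genes$gene_end[i] + 1000)
  }
  p <- runif(nrow(snps))
  if (cfg$gwas_spike && any(near)) {
    p[near] <- rbeta(sum(near), cfg$spike_beta_a, 1)
  }
  snps$pvalue <- pmin(pmax(p, 1e-300), 1)
  adapt <- (near & runif(nrow(snps)) < cfg$p_adapt) |
    (!near & runif(nrow(snps)) < cfg$p_adapt_bg)
  snps <- snps[c("snp_id", "chrom", "pos", "maf", "pvalue")]
  if (cfg$n_individuals > 0) {
    geno <- vapply(seq_len(cfg$n_individuals), function(j) {
      rbinom(nrow(snps), 2, snps$maf)
    }, numeric(nrow(snps)))
    colnames(geno) <- sprintf("ind%03d", seq_len(cfg$n_individuals))
    snps <- cbind(snps, as.data.frame(geno))
  }
  list(snps = snps, adaptation_snp_ids = snps$snp_id[adapt],
       near_ddr = near)
}

#' Simulate a complete study
#'
#' Seeds once from `cfg$seed` (if set) and generates the pangenome,
#' field and chamber expression, promoters, and SNP tables in a fixed
#' order, so the whole study is reproducible from the single seed.
#'
#' @param cfg a [sim_config()].
#' @return list: cfg, pangenome components (inbreds, genes, members,
#'   haplotypes, truth), expression_field, expression_chamber,
#'   promoters, snps, adaptation_snp_ids.
#' @export
simulate_study <- function(cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pan <- simulate_pangenome(cfg)
  expr_field <- simulate_expression(cfg, pan, "field")
  expr_chamber <- simulate_expression(cfg, pan, "chamber")
  prom <- simulate_promoters(cfg, pan)
  snp <- simulate_snps(cfg, pan)
  c(list(cfg = cfg), pan,
    list(expression_field = expr_field,
         expression_chamber = expr_chamber,
         promoters = prom,
         snps = snp$snps,
         adaptation_snp_ids = snp$adaptation_snp_ids))
}
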