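test_that("configuration is validated with the offending field named", {
  expect_error(sim_config(dispersion = 1.2), "dispersion")
  expect_error(sim_config(planted_rho = 0), "planted_rho")
  expect_error(sim_config(kmer_k = 14), "kmer_k")
  expect_error(sim_config(genes_per_chromosome = c(5, 5)),
               "genes_per_chromosome")
  expect_error(sim_config(long_read_error = -0.1), "long_read_error")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("the same seed reproduces every simulation stream exactly", {
  cfg <- small_cfg(seed = 42)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  for (el in c("sites", "annotation", "counts", "long_reads", "expression",
               "contigs", "female_reads", "truth")) {
    expect_identical(a[[el]], b[[el]])
  }
  expect_false(identical(simulate_study(small_cfg(seed = 43))$sites, a$sites))
})

test_that("truth records are conserved: one per gene, site and contig", {
  cfg <- small_cfg()
  study <- simulate_study(cfg)
  expect_identical(nrow(study$truth$genes),
                   as.integer(sum(cfg$genes_per_chromosome)))
  expect_identical(study$truth$genes$gene_id, study$annotation$gene_id)
  expect_identical(nrow(study$truth$sites), nrow(study$sites))
  expect_identical(sort(study$truth$contigs$contig_id),
                   sort(names(study$contigs)))
})

test_that("without planted divergence the het statistic is centred at 50 everywhere", {
  cfg <- small_cfg(genes_per_chromosome = c(I = 120, III = 120, X = 120),
                   frac_div_genes_III = 0, cluster_artifact_rate = 0,
                   seed = 7)
  sim <- simulate_variants(cfg)
  het <- suppressMessages(gene_het_summaries(sim$sites))
  means <- tapply(het$pct_IIIM_het, het$chromosome, mean)
  # symmetric construction: mean within a few points of 50 on every chromosome
  expect_true(all(abs(means - 50) < 6))
  expect_false(any(sim$truth$genes$divergent))
})

test_that("with full planted divergence and many het sites every third-chromosome gene leans genotypic", {
  cfg <- small_cfg(genes_per_chromosome = c(I = 40, III = 40),
                   frac_div_genes_III = 1, het_site_rate = 50, seed = 8)
  sim <- simulate_variants(cfg)
  het <- suppressMessages(gene_het_summaries(sim$sites))
  iii <- het[het$chromosome == "III", ]
  expect_true(all(iii$h_G > iii$h_SR))
})

test_that("allele counts are unbiased around the planted fraction", {
  # binomial-SD oracle: pooled fraction within 3 exact binomial SDs
  for (rho in c(0.5, 0.8)) {
    cfg <- small_cfg(genes_per_chromosome = c(III = 60),
                     frac_div_genes_III = if (rho == 0.5) 0 else 1,
                     planted_rho = if (rho == 0.5) 0.8 else rho,
                     dispersion = 0, depth_mean = 100, seed = 9)
    sim <- simulate_variants(cfg)
    counts <- simulate_allele_counts(cfg, sim$truth)
    cg <- counts[counts$group == "genotypic", ]
    tg <- sim$truth$genes
    # orient each gene's counts to the planted proto-Y haplotype
    ori <- tg$focal_is_IIIM[match(cg$gene_id, tg$gene_id)]
    foc <- ifelse(ori, cg$focal_count, cg$total_count - cg$focal_count)
    total <- sum(cg$total_count)
    sd3 <- 3 * sqrt(rho * (1 - rho) / total)
    expect_lt(abs(sum(foc) / total - rho), sd3)
  }
})

test_that("zero depth gives all-zero counts that the read filter later drops", {
  cfg <- small_cfg(genes_per_chromosome = c(III = 10), depth_mean = 0)
  sim <- simulate_variants(cfg)
  counts <- simulate_allele_counts(cfg, sim$truth)
  expect_true(all(counts$total_count == 0))
  expect_true(all(counts$focal_count == 0))
  expect_false(any(min_read_filter(counts)$retained))
})

test_that("error-free long reads are each consistent with exactly one true haplotype", {
  cfg <- small_cfg(genes_per_chromosome = c(III = 30), frac_div_genes_III = 1,
                   long_read_error = 0, seed = 10)
  sim <- simulate_variants(cfg)
  lr <- simulate_long_reads(cfg, sim$truth)
  ts <- sim$truth$sites
  for (rid in unique(lr$read_id)) {
    obs <- lr[lr$read_id == rid, ]
    j <- match(obs$position, ts$position)
    m_y <- all(obs$allele == ts$IIIM_allele[j])
    m_x <- all(obs$allele == ts$III_allele[j])
    if (!xor(m_y, m_x)) {
      # single-site reads of shared alleles match both haplotype labels
      expect_true(m_y || m_x)
    } else {
      expect_true(xor(m_y, m_x))
    }
  }
})

test_that("reads with 50% flip error carry no phasing information", {
  cfg <- small_cfg(genes_per_chromosome = c(III = 60), frac_div_genes_III = 1,
                   het_site_rate = 6, long_read_error = 0.5, seed = 12)
  sim <- simulate_variants(cfg)
  lr <- simulate_long_reads(cfg, sim$truth)
  ds <- truth_diag_sites(sim$truth)
  haps <- phase_haplotypes(lr, ds)
  ts <- sim$truth$sites
  agree <- vapply(haps, function(h) {
    j <- match(h$positions, ts$position)
    hap_agreement(h, ts$IIIM_allele[j], ts$III_allele[j])
  }, 0)
  multi <- vapply(haps, function(h) length(h$positions) > 1, TRUE)
  # site-level agreement (best orientation) hovers near the random baseline;
  # far below the accuracy achieved at realistic error rates
  expect_lt(mean(agree[multi]), 0.92)
})

test_that("the planted discordant candidate is a divergent third-chromosome gene", {
  cfg <- small_cfg(frac_div_genes_III = 0.2)
  study <- simulate_study(cfg)
  cand <- study$truth$candidate
  expect_false(is.na(cand))
  g <- study$truth$genes
  expect_true(g$divergent[g$gene_id == cand])
  expect_identical(g$chromosome[g$gene_id == cand], "III")
  ex <- study$expression
  expect_identical(ex$bias_genotypic[ex$gene_id == cand], "male-biased")
  expect_identical(ex$bias_sexreversed[ex$gene_id == cand], "female-biased")
  # all other genes are concordant
  other <- ex[ex$gene_id != cand, ]
  expect_true(all(other$bias_genotypic == other$bias_sexreversed))
})
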