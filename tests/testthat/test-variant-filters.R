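mk_sites <- function(pos, class = "SNP", FS = 1, QD = 10, chrom = "III",
                     gene = "g1") {
  n <- length(pos)
  data.frame(chromosome = rep_len(chrom, n), position = pos,
             variant_class = rep_len(class, n), gene_id = rep_len(gene, n),
             FS = rep_len(FS, n), QD = rep_len(QD, n),
             stringsAsFactors = FALSE)
}

test_that("3 SNPs spanning 35 bp are removed; well-spaced SNPs are retained", {
  s <- mk_sites(c(100, 110, 134))  # span 35 bp inclusive
  expect_identical(nrow(hard_filter_variants(s)), 0L)
  s2 <- mk_sites(c(100, 110, 135))  # span 36 bp: no cluster
  expect_identical(nrow(hard_filter_variants(s2)), 3L)
  s3 <- mk_sites(c(100, 200, 300))
  expect_identical(hard_filter_variants(s3)$position, c(100, 200, 300))
})

test_that("FS and QD thresholds are strict inequalities", {
  s <- mk_sites(c(100, 500, 900, 1300), FS = c(25, 20, 1, 1),
                QD = c(10, 10, 2, 1.999))
  out <- hard_filter_variants(s)
  expect_identical(out$position, c(500, 900))  # FS=20 and QD=2 survive
})

test_that("missing FS/QD pass the quality filters with a warning", {
  s <- mk_sites(c(100, 500), FS = c(NA, 1), QD = c(10, NA))
  expect_warning(out <- hard_filter_variants(s), "missing FS or QD")
  expect_identical(nrow(out), 2L)
})

test_that("unsorted input is rejected with advice to sort", {
  s <- mk_sites(c(200, 100))
  expect_error(hard_filter_variants(s), "sort")
  s2 <- rbind(mk_sites(100, chrom = "I"), mk_sites(100, chrom = "II"),
              mk_sites(100, chrom = "I"))
  expect_error(cluster_bias_filter(s2), "sort")
})

test_that("indels are exempt from the cluster filter and do not seed clusters", {
  s <- mk_sites(c(100, 110, 134), class = c("SNP", "indel", "SNP"))
  out <- cluster_bias_filter(s)  # only 2 SNPs within the window
  expect_identical(nrow(out), 3L)
  s2 <- mk_sites(c(100, 105, 110, 134), class = c("SNP", "indel", "SNP", "SNP"))
  out2 <- cluster_bias_filter(s2)
  expect_identical(out2$position, 105)  # the 3 SNPs go, the indel stays
})

test_that("cluster filtering is idempotent, empty-safe and never adds sites", {
  expect_identical(nrow(cluster_bias_filter(mk_sites(integer(0)))), 0L)
  cfg <- small_cfg(cluster_artifact_rate = 0.5)
  sites <- simulate_variants(cfg)$sites
  once <- cluster_bias_filter(sites)
  twice <- cluster_bias_filter(once)
  attr(once, "log") <- NULL
  attr(twice, "log") <- NULL
  expect_identical(once, twice)
  expect_lte(nrow(once), nrow(sites))
  key <- function(x) paste(x$chromosome, x$position)
  expect_true(all(key(once) %in% key(sites)))
})

test_that("cluster filter matches the brute-force all-windows oracle on random inputs", {
  set.seed(301)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    s <- data.frame(chromosome = sample(c("I", "II"), n, replace = TRUE),
                    position = sample.int(300, n),
                    variant_class = sample(c("SNP", "indel"), n, TRUE,
                                           prob = c(0.85, 0.15)),
                    FS = 1, QD = 10, stringsAsFactors = FALSE)
    s <- s[order(s$chromosome, s$position), ]
    s <- s[!duplicated(paste(s$chromosome, s$position)), ]
    keep_oracle <- !oracle_cluster_members(s$chromosome, s$position,
                                           s$variant_class == "SNP")
    out <- cluster_bias_filter(s)
    expect_identical(out$position, s$position[keep_oracle])
  }
})

test_that("a heavily artifact-laden simulation retains roughly the planted clean fraction", {
  cfg <- small_cfg(genes_per_chromosome = c(III = 300), het_site_rate = 1,
                   cluster_artifact_rate = 1, indel_rate = 0, seed = 77)
  sim <- simulate_variants(cfg)
  snps <- sim$sites$variant_class == "SNP"
  retained <- nrow(cluster_bias_filter(sim$sites[snps, , drop = FALSE]))
  planted_clean <- mean(!sim$truth$sites$cluster_artifact[snps])
  expect_equal(retained / sum(snps), planted_clean, tolerance = 0.02)
  # with one artifact cluster per gene and few real sites, most SNPs are
  # artifacts, mirroring an aggressive real-data retention rate
  expect_lt(retained / sum(snps), 0.5)
})

test_that("percent heterozygosity follows the formula at its limits", {
  s <- data.frame(chromosome = "I", position = 1:10, gene_id = "gA",
                  gt_G = rep("A/A", 10), gt_SR = rep("A/G", 10))
  expect_identical(gene_het_summaries(s)$pct_IIIM_het, 0)
  s$gt_G <- "A/G"; s$gt_SR <- "A/A"
  expect_identical(gene_het_summaries(s)$pct_IIIM_het, 100)
  s$gt_SR <- c(rep("A/G", 5), rep("A/A", 5))
  s$gt_G <- c(rep("A/A", 5), rep("A/G", 5))
  expect_identical(gene_het_summaries(s)$pct_IIIM_het, 50)
})

test_that("genes with no heterozygous sites are excluded with a message", {
  s <- data.frame(chromosome = "I", position = c(1, 2),
                  gene_id = c("gA", "gB"),
                  gt_G = c("A/G", "C/C"), gt_SR = c("A/A", "C/C"))
  expect_message(out <- gene_het_summaries(s), "excluded")
  expect_identical(out$gene_id, "gA")
})

test_that("summaries equal an independent recount from the written VCF text", {
  cfg <- small_cfg(genes_per_chromosome = c(I = 20, III = 20))
  sim <- simulate_variants(cfg)
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(sim$sites, path)
  # independent recount: parse the VCF text directly
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  gene <- sub(".*GENE=([^;]+).*", "\\1", vapply(fields, `[`, "", 8))
  het_of <- function(col) {
    gt <- vapply(fields, `[`, "", col)
    a <- substr(gt, 1, 1); b <- substr(gt, 3, 3)
    a != b
  }
  hg <- tapply(het_of(10), gene, sum)
  hsr <- tapply(het_of(11), gene, sum)
  pct_oracle <- 100 * hg / (hg + hsr)
  pct_oracle <- pct_oracle[hg + hsr > 0]
  out <- suppressMessages(gene_het_summaries(sim$sites))
  expect_equal(out$pct_IIIM_het, as.numeric(pct_oracle[out$gene_id]))
})

test_that("diagnostic sites get the shared allele as III and the unique one as III^M", {
  s <- data.frame(chromosome = "III", position = c(10, 20, 30, 40),
                  gene_id = "g1",
                  gt_G = c("A/G", "A/A", "A/G", "C/G"),
                  gt_SR = c("A/A", "A/A", "A/G", "T/T"),
                  stringsAsFactors = FALSE)
  expect_message(out <- find_diagnostic_sites(s), "triallelic")
  # only position 10 qualifies: 20 is hom/hom, 30 shared-het, 40 triallelic
  expect_identical(out$position, 10)
  expect_identical(out$III_allele, "A")
  expect_identical(out$IIIM_allele, "G")
})

test_that("planted divergence raises the third-chromosome median above background", {
  cfg <- small_cfg(genes_per_chromosome = c(I = 80, II = 80, III = 80),
                   frac_div_genes_III = 0.5, seed = 21)
  sim <- simulate_variants(cfg)
  het <- suppressMessages(gene_het_summaries(hard_filter_variants(sim$sites),
                                             sim$annotation))
  med <- tapply(het$pct_IIIM_het, het$chromosome, median)
  expect_gt(med[["III"]], max(med[["I"]], med[["II"]]))
})
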