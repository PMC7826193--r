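test_that("the Wilcoxon contrast behaves under exchangeable and shifted data", {
  vals <- c(10, 20, 30, 40, 50, 60)
  s <- data.frame(gene_id = letters[1:12],
                  chromosome = rep(c("III", "I"), each = 6),
                  pct_IIIM_het = c(vals, vals))
  t0 <- het_chromosome_test(s, "III", "I")
  expect_gt(t0$p_value, 0.99)
  expect_identical(t0$sidedness, "two-sided")
  # planted +20-point shift, 200 genes per side: overwhelming rejection
  set.seed(401)
  for (i in 1:10) {
    bg <- pmin(pmax(rnorm(200, 50, 15), 0), 100)
    fg <- pmin(pmax(rnorm(200, 70, 15), 0), 100)
    s2 <- data.frame(gene_id = paste0("g", 1:400),
                     chromosome = rep(c("III", "I"), each = 200),
                     pct_IIIM_het = c(fg, bg))
    expect_lt(het_chromosome_test(s2, "III", "I")$p_value, 0.001)
  }
  expect_error(het_chromosome_test(s, "V", "I"), "at least 2")
})

test_that("Fisher's exact test validates input and matches known values", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))$p_value, 1)
  # 2 extreme tables out of choose(10,5) equally-likely arrangements
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-10)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
  # sample odds ratio, not the conditional MLE
  expect_equal(fisher_exact_2x2(matrix(c(10, 5, 4, 8), 2,
                                       byrow = TRUE))$statistic, 4)
})

test_that("Fisher p-values agree with hypergeometric enumeration on random tables", {
  set.seed(402)
  for (i in 1:300) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-8)
  }
})

test_that("the ASE contingency counts the four discordance cells", {
  mk <- function(gene, chrom, cls) {
    data.frame(gene_id = gene, chromosome = chrom, group = "x",
               prop_gt_half = 0.5, bin = "non-ASE", ase_class = cls,
               stringsAsFactors = FALSE)
  }
  g <- rbind(mk(paste0("t", 1:5), "III", "ASE"),
             mk(paste0("u", 1:3), "III", "non-ASE"),
             mk(paste0("v", 1:4), "I", "ASE"),
             mk(paste0("w", 1:2), "I", "moderate"))
  s <- rbind(mk(paste0("t", 1:5), "III", "non-ASE"),
             mk(paste0("u", 1:3), "III", "ASE"),
             mk(paste0("v", 1:4), "I", "non-ASE"),
             mk(paste0("w", 1:2), "I", "non-ASE"))
  ct <- build_ase_contingency(g, s)
  expect_identical(c(ct$a, ct$b, ct$c, ct$d), c(5L, 3L, 4L, 0L))
  expect_setequal(ct$genes_a, paste0("t", 1:5))
  # moderate genes belong to neither cell
  expect_false(any(paste0("w", 1:2) %in% c(ct$genes_c, ct$genes_d)))
  # swapping the groups swaps a<->b and c<->d
  ct2 <- build_ase_contingency(s, g)
  expect_identical(c(ct2$a, ct2$b, ct2$c, ct2$d),
                   c(ct$b, ct$a, ct$d, ct$c))
  # all-non-ASE input gives an empty table
  ct0 <- build_ase_contingency(s, s)
  expect_identical(c(ct0$a, ct0$b, ct0$c, ct0$d), rep(0L, 4))
})

test_that("genes classified in only one group are excluded with a message", {
  g <- data.frame(gene_id = c("a", "b"), chromosome = "III", group = "x",
                  prop_gt_half = 0.9, bin = "extreme-high", ase_class = "ASE")
  s <- data.frame(gene_id = "a", chromosome = "III", group = "y",
                  prop_gt_half = 0.5, bin = "non-ASE", ase_class = "non-ASE")
  expect_message(ct <- build_ase_contingency(g, s), "one group")
  expect_identical(ct$n_genes, 1L)
  expect_identical(ct$a, 1L)
})

test_that("contingency counts match a direct count on planted truth labels", {
  cfg <- small_cfg(genes_per_chromosome = c(I = 40, III = 40),
                   frac_div_genes_III = 0.3, seed = 19)
  sim <- simulate_variants(cfg)
  counts <- simulate_allele_counts(cfg, sim$truth)
  fg <- ase_fit(counts[counts$group == "genotypic", ], seed = 19)
  fs <- ase_fit(counts[counts$group == "sexreversed", ], seed = 20)
  ct <- suppressMessages(build_ase_contingency(fg, fs, sim$annotation))
  # direct count oracle over the joined classifications
  rg <- fg$results; rs <- fs$results
  common <- intersect(rg$gene_id, rs$gene_id)
  cg <- rg$ase_class[match(common, rg$gene_id)]
  cs <- rs$ase_class[match(common, rs$gene_id)]
  on3 <- sim$truth$genes$chromosome[match(common,
                                          sim$truth$genes$gene_id)] == "III"
  expect_identical(ct$a, sum(on3 & cg == "ASE" & cs == "non-ASE"))
  expect_identical(ct$b, sum(on3 & cs == "ASE" & cg == "non-ASE"))
  expect_identical(ct$c, sum(!on3 & cg == "ASE" & cs == "non-ASE"))
  expect_identical(ct$d, sum(!on3 & cs == "ASE" & cg == "non-ASE"))
  # a + b + c + d never exceeds the genes classified in both groups
  expect_lte(ct$a + ct$b + ct$c + ct$d, length(common))
  # most planted divergent genes land in cell a
  div <- sim$truth$genes$gene_id[sim$truth$genes$divergent]
  expect_gt(mean(div %in% ct$genes_a), 0.6)
})

test_that("discordant expression is the male/female label swap only", {
  ex <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    bias_genotypic = c("male-biased", "male-biased", "unbiased",
                       "female-biased", "female-biased"),
    bias_sexreversed = c("female-biased", "male-biased", "female-biased",
                         "male-biased", "female-biased"))
  expect_setequal(classify_discordant(ex), c("a", "d"))
})

test_that("candidate intersection combines the two screens", {
  expect_identical(intersect_candidates(character(0), c("a", "b")),
                   character(0))
  expect_identical(intersect_candidates(c("a", "z"), c("a", "b")), "a")
  expect_identical(intersect_candidates(c("x", "y"), c("a", "b")),
                   character(0))
})

test_that("fold-change labels use the documented threshold", {
  out <- sex_bias_labels(c(1.5, 0.2, -2), c(-1, 0, -1.2))
  expect_identical(out$bias_genotypic,
                   c("male-biased", "unbiased", "female-biased"))
  expect_identical(out$bias_sexreversed,
                   c("female-biased", "unbiased", "female-biased"))
})

test_that("detection of the contingency signal strengthens with the planted fraction", {
  pvals <- vapply(c(0.05, 0.3, 0.8), function(fr) {
    cfg <- small_cfg(genes_per_chromosome = c(I = 60, II = 60, III = 60),
                     frac_div_genes_III = fr, seed = 23)
    sim <- simulate_variants(cfg)
    counts <- simulate_allele_counts(cfg, sim$truth)
    fg <- ase_fit(counts[counts$group == "genotypic", ], seed = 23)
    fs <- ase_fit(counts[counts$group == "sexreversed", ], seed = 24)
    ct <- suppressMessages(build_ase_contingency(fg, fs, sim$annotation))
    fisher_exact_2x2(ct)$p_value
  }, 0)
  expect_true(all(diff(pvals) < 0))
  expect_lt(pvals[3], 0.001)
})
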