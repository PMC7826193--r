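new_test_result <- function(test, statistic, p_value, sizes, sidedness,
                            extra = list()) {
  out <- c(list(test = test, statistic = statistic, p_value = p_value,
                sizes = sizes, sidedness = sidedness), extra)
  class(out) <- "protoY_test"
  out
}

#' @export
print.protoY_test <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$test, x$sidedness))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$sizes)) {
    cat("  sizes:", paste(names(x$sizes), unlist(x$sizes), sep = "=",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Chromosome-level heterozygosity contrast
#'
#' Two-sided Wilcoxon rank-sum test comparing the per-gene percent of
#' heterozygous sites attributable to genotypic males (`pct_IIIM_het`)
#' between genes on the focal chromosome(s) and genes on the background
#' chromosomes. The two contrasts of interest are third chromosome vs all
#' others, and X vs autosomes I, II, IV, V.
#'
#' @param summaries Output of [gene_het_summaries()].
#' @param focal_chromosomes,background_chromosomes Chromosome name vectors.
#' @return A `protoY_test` result (statistic, two-sided p-value, group
#'   sizes and medians).
#' @examples
#' s <- data.frame(gene_id = letters[1:6],
#'                 chromosome = rep(c("III", "I"), each = 3),
#'                 pct_IIIM_het = c(80, 90, 75, 50, 45, 55))
#' het_chromosome_test(s, "III", "I")
#' @export
het_chromosome_test <- function(summaries, focal_chromosomes,
                                background_chromosomes) {
  x <- summaries$pct_IIIM_het[summaries$chromosome %in% focal_chromosomes]
  y <- summaries$pct_IIIM_het[summaries$chromosome %in% background_chromosomes]
  if (length(x) < 2 || length(y) < 2) {
    stop("each side of the heterozygosity contrast needs at least 2 genes")
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  new_test_result(
    sprintf("Wilcoxon rank-sum: %%het on %s vs %s",
            paste(focal_chromosomes, collapse = ","),
            paste(background_chromosomes, collapse = ",")),
    unname(wt$statistic), wt$p.value,
    list(n_focal = length(x), n_background = length(y)), "two-sided",
    extra = list(median_focal = median(x), median_background = median(y)))
}

#' Cross-genotype ASE contingency table
#'
#' Counts genes whose ASE classification differs between the genotypes:
#' `a` = focal-chromosome genes with ASE in genotypic males that are
#' non-ASE in sex-reversed males, `b` = the reverse pattern on the focal
#' chromosome, and `c`, `d` = the same two counts over all other
#' chromosomes. Only genes classified in both groups enter; genes in a
#' moderate bin in the relevant group belong to neither cell.
#'
#' @param ase_genotypic,ase_sexreversed `ase_fit` objects (or their
#'   `results` data frames) for the two groups.
#' @param annotation Gene annotation with gene_id and chromosome; optional
#'   if the results carry a chromosome column.
#' @param focal_chromosome Chromosome name of the proto-sex chromosome.
#' @return An object of class `ase_contingency`: counts `a`-`d`, the member
#'   gene ids per cell, and `table` (the 2x2 matrix rows = focal/other
#'   chromosomes, cols = the two discordance directions).
#' @export
build_ase_contingency <- function(ase_genotypic, ase_sexreversed,
                                  annotation = NULL,
                                  focal_chromosome = "III") {
  rg <- if (inherits(ase_genotypic, "ase_fit")) ase_genotypic$results else
    ase_genotypic
  rs <- if (inherits(ase_sexreversed, "ase_fit")) ase_sexreversed$results else
    ase_sexreversed
  common <- intersect(rg$gene_id, rs$gene_id)
  dropped <- length(setdiff(union(rg$gene_id, rs$gene_id), common))
  if (dropped > 0) {
    message(dropped, " gene(s) classified in only one group excluded")
  }
  rg <- rg[match(common, rg$gene_id), , drop = FALSE]
  rs <- rs[match(common, rs$gene_id), , drop = FALSE]
  chrom <- rg$chromosome
  if ((is.null(chrom) || anyNA(chrom)) && !is.null(annotation)) {
    chrom <- annotation$chromosome[match(common, annotation$gene_id)]
  }
  if (is.null(chrom) || anyNA(chrom)) {
    stop("chromosome unknown for some genes; supply an annotation")
  }
  focal <- chrom == focal_chromosome
  g_ase <- rg$ase_class == "ASE"
  g_non <- rg$ase_class == "non-ASE"
  s_ase <- rs$ase_class == "ASE"
  s_non <- rs$ase_class == "non-ASE"
  cell <- function(sel) common[sel]
  genes_a <- cell(focal & g_ase & s_non)
  genes_b <- cell(focal & s_ase & g_non)
  genes_c <- cell(!focal & g_ase & s_non)
  genes_d <- cell(!focal & s_ase & g_non)
  tab <- matrix(c(length(genes_a), length(genes_b),
                  length(genes_c), length(genes_d)),
                nrow = 2, byrow = TRUE,
                dimnames = list(chromosome = c(focal_chromosome, "other"),
                                pattern = c("ASE.G/non.SR", "ASE.SR/non.G")))
  out <- list(a = length(genes_a), b = length(genes_b), c = length(genes_c),
              d = length(genes_d), table = tab, genes_a = genes_a,
              genes_b = genes_b, genes_c = genes_c, genes_d = genes_d,
              focal_chromosome = focal_chromosome, n_genes = length(common))
  class(out) <- "ase_contingency"
  out
}

#' @export
print.ase_contingency <- function(x, ...) {
  cat(sprintf("ASE discordance contingency (%s vs other chromosomes, %d genes classified in both groups)\n",
              x$focal_chromosome, x$n_genes))
  print(x$table)
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the standard rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. Also reports the sample odds ratio `ad / bc`.
#'
#' @param table A 2x2 matrix of non-negative integer counts, or an
#'   `ase_contingency` object.
#' @return A `protoY_test` result with the odds ratio as statistic.
#' @examples
#' fisher_exact_2x2(matrix(c(95, 76, 241, 281), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  if (inherits(table, "ase_contingency")) table <- table$table
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)) || anyNA(tab)) {
    stop("table entries must be non-negative integers")
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  new_test_result("Fisher's exact test (2x2)", or, ft$p.value,
                  list(N = sum(tab)), "two-sided",
                  extra = list(table = tab))
}

#' Genes with discordant sex-biased expression
#'
#' Returns genes that are male-biased relative to phenotypic females in one
#' male genotype and female-biased in the other -- the expression signature
#' of cis-regulatory divergence between the proto-Y and proto-X alleles.
#'
#' @param expression_records Data frame gene_id, bias_genotypic,
#'   bias_sexreversed with labels in male-biased / female-biased / unbiased.
#' @return Character vector of gene ids.
#' @export
classify_discordant <- function(expression_records) {
  g <- expression_records$bias_genotypic
  s <- expression_records$bias_sexreversed
  disc <- (g == "male-biased" & s == "female-biased") |
    (g == "female-biased" & s == "male-biased")
  expression_records$gene_id[disc]
}

#' Intersect the discordant-expression and ASE-discordance screens
#'
#' Candidate proto-Y regulatory-divergence genes: third-chromosome genes
#' with ASE in genotypic males and non-ASE in sex-reversed males that also
#' show discordant sex-biased expression.
#'
#' @param discordant_genes Gene ids from [classify_discordant()].
#' @param ase_contingency An `ase_contingency` object (its `genes_a` cell),
#'   or a character vector of gene ids.
#' @return Character vector of candidate gene ids.
#' @export
intersect_candidates <- function(discordant_genes, ase_contingency) {
  members <- if (inherits(ase_contingency, "ase_contingency")) {
    ase_contingency$genes_a
  } else {
    ase_contingency
  }
  intersect(discordant_genes, members)
}

#' Sex-bias labels from fold changes (convenience)
#'
#' Derives the three-level bias labels from log2 fold changes of each male
#' genotype against phenotypic females, using a fixed threshold. This is a
#' convenience for data lacking precomputed labels; the screen itself
#' consumes labels from an upstream differential-expression analysis.
#'
#' @param log2fc_genotypic,log2fc_sexreversed Numeric vectors of log2 fold
#'   changes (male vs female).
#' @param threshold Absolute log2 fold-change threshold (default 1).
#' @return A data frame of bias labels for both genotypes.
#' @export
sex_bias_labels <- function(log2fc_genotypic, log2fc_sexreversed,
                            threshold = 1) {
  lab <- function(x) {
    ifelse(x >= threshold, "male-biased",
           ifelse(x <= -threshold, "female-biased", "unbiased"))
  }
  data.frame(bias_genotypic = lab(log2fc_genotypic),
             bias_sexreversed = lab(log2fc_sexreversed),
             stringsAsFactors = FALSE)
}
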