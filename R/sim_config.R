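#' Configuration for the synthetic study generator
#'
#' Builds a validated configuration describing the simulated study: two
#' genotype groups (genotypic `III^M/III` males and sex-reversed `III/III`
#' males), three RNA-seq replicates each, six chromosomes (I-V, X), with
#' cis-regulatory divergence planted in a fraction of third-chromosome genes
#' in the genotypic group only.
#'
#' Defaults are desk-scale: 200 genes per autosome and 100 on the gene-poor
#' X. Set `genes_per_chromosome` upward (the third chromosome of the study
#' organism carries ~2,500 genes) to approach study scale.
#'
#' @param genes_per_chromosome Named integer vector, chromosome name ->
#'   number of genes.
#' @param n_replicates Replicates per genotype group.
#' @param depth_mean Expected reads per gene per replicate over diagnostic
#'   sites (Poisson mean).
#' @param dispersion Beta-binomial overdispersion of allele counts in
#'   `[0, 1)`; 0 gives pure binomial sampling.
#' @param frac_div_genes_III Fraction of third-chromosome genes with planted
#'   cis divergence (elevated focal allele fraction) in genotypic males.
#' @param planted_rho Allele fraction of the proto-Y haplotype for divergent
#'   genes, in `(0, 1)`.
#' @param het_site_rate Expected heterozygous sites per gene per group.
#' @param cluster_artifact_rate Per-gene rate of planted 3-SNP/35-bp
#'   mapping-artifact clusters.
#' @param long_read_depth Long reads per gene for phasing.
#' @param long_read_error Per-site allele flip probability in long reads,
#'   in `[0, 1)`.
#' @param kmer_k k-mer length for the proto-Y contig screen (odd, 3-31).
#' @param indel_rate Fraction of background variant sites simulated as small
#'   indels (exempt from the SNP-cluster filter).
#' @param fs_fail_rate,qd_fail_rate Fractions of sites planted with failing
#'   Fisher-strand (FS > 20) or quality-by-depth (QD < 2) annotations.
#' @param n_shared_contigs,n_male_contigs,n_mixed_contigs Assembly contigs of
#'   each class: shared with the female genome, fully male-specific, and
#'   half-and-half.
#' @param contig_length,female_genome_length,female_read_length Sequence
#'   lengths (bp) for the contig simulation.
#' @param plant_discordant If `TRUE` and at least one divergent gene exists,
#'   the first divergent third-chromosome gene is given discordant sex-biased
#'   expression labels (male-biased in genotypic males, female-biased in
#'   sex-reversed males), creating one true end-to-end candidate.
#' @param seed Integer seed; all simulation streams derive from it.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(genes_per_chromosome = c(I = 20, III = 20, X = 10),
#'                   seed = 7)
#' cfg
#' @export
sim_config <- function(genes_per_chromosome = c(I = 200, II = 200, III = 200,
                                                IV = 200, V = 200, X = 100),
                       n_replicates = 3,
                       depth_mean = 50,
                       dispersion = 0.02,
                       frac_div_genes_III = 0.1,
                       planted_rho = 0.8,
                       het_site_rate = 4,
                       cluster_artifact_rate = 0.2,
                       long_read_depth = 20,
                       long_read_error = 0.05,
                       kmer_k = 15,
                       indel_rate = 0.1,
                       fs_fail_rate = 0.03,
                       qd_fail_rate = 0.03,
                       n_shared_contigs = 6,
                       n_male_contigs = 3,
                       n_mixed_contigs = 1,
                       contig_length = 450,
                       female_genome_length = 6000,
                       female_read_length = 120,
                       plant_discordant = TRUE,
                       seed = 1) {
  cfg <- list(genes_per_chromosome = genes_per_chromosome,
              n_replicates = n_replicates,
              depth_mean = depth_mean,
              dispersion = dispersion,
              frac_div_genes_III = frac_div_genes_III,
              planted_rho = planted_rho,
              het_site_rate = het_site_rate,
              cluster_artifact_rate = cluster_artifact_rate,
              long_read_depth = long_read_depth,
              long_read_error = long_read_error,
              kmer_k = kmer_k,
              indel_rate = indel_rate,
              fs_fail_rate = fs_fail_rate,
              qd_fail_rate = qd_fail_rate,
              n_shared_contigs = n_shared_contigs,
              n_male_contigs = n_male_contigs,
              n_mixed_contigs = n_mixed_contigs,
              contig_length = contig_length,
              female_genome_length = female_genome_length,
              female_read_length = female_read_length,
              plant_discordant = isTRUE(plant_discordant),
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why),
         call. = FALSE)
  }
  g <- cfg$genes_per_chromosome
  if (length(g) < 1 || is.null(names(g)) || any(!nzchar(names(g)))) {
    fail("genes_per_chromosome", "must be a named vector of gene counts")
  }
  if (any(g < 0) || any(g != round(g))) {
    fail("genes_per_chromosome", "counts must be non-negative integers")
  }
  unit <- function(field, lo_ok = TRUE) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        x < 0 || x >= 1 || (!lo_ok && x <= 0)) {
      fail(field, "must be a single value in [0, 1)")
    }
  }
  unit("dispersion")
  fd <- cfg$frac_div_genes_III
  if (!is.numeric(fd) || length(fd) != 1 || is.na(fd) || fd < 0 || fd > 1) {
    fail("frac_div_genes_III", "must be a single value in [0, 1]")
  }
  unit("long_read_error")
  unit("indel_rate")
  unit("fs_fail_rate")
  unit("qd_fail_rate")
  if (!is.numeric(cfg$planted_rho) || cfg$planted_rho <= 0 ||
      cfg$planted_rho >= 1) {
    fail("planted_rho", "must be in (0, 1)")
  }
  for (field in c("n_replicates", "depth_mean", "het_site_rate",
                  "cluster_artifact_rate", "long_read_depth",
                  "n_shared_contigs", "n_male_contigs", "n_mixed_contigs",
                  "contig_length", "female_genome_length",
                  "female_read_length")) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
      fail(field, "must be a single non-negative number")
    }
  }
  if (cfg$cluster_artifact_rate > 1) {
    fail("cluster_artifact_rate", "must be in [0, 1]")
  }
  k <- cfg$kmer_k
  if (!is.numeric(k) || length(k) != 1 || k < 3 || k > 31 || k %% 2 != 1) {
    fail("kmer_k", "must be an odd integer between 3 and 31")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    fail("seed", "must be a single integer")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat("  chromosomes:",
      paste(sprintf("%s (%d genes)", names(x$genes_per_chromosome),
                    x$genes_per_chromosome), collapse = ", "), "\n")
  cat(sprintf("  %d replicates/group, depth %g reads/gene/replicate, dispersion %g\n",
              x$n_replicates, x$depth_mean, x$dispersion))
  cat(sprintf("  planted divergence: %.0f%% of III genes at rho = %g\n",
              100 * x$frac_div_genes_III, x$planted_rho))
  cat(sprintf("  het sites/gene/group %g; cluster artifact rate %g; indel rate %g\n",
              x$het_site_rate, x$cluster_artifact_rate, x$indel_rate))
  cat(sprintf("  long reads: depth %g, flip error %g; k-mer k = %d; seed %d\n",
              x$long_read_depth, x$long_read_error, as.integer(x$kmer_k),
              as.integer(x$seed)))
  invisible(x)
}
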