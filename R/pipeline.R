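#' Run the full proto-Y divergence analysis
#'
#' Executes the analysis stages in order: variant hard-filtering, per-gene
#' heterozygosity summaries and chromosome contrasts, the ASE-specific SNP
#' cluster filter, diagnostic-site assignment, haplotype phasing, per-group
#' ASE fitting and classification, the cross-genotype ASE contingency with
#' Fisher's exact test, per-chromosome ASE-proportion contrasts, the
#' discordant sex-biased expression screen with the final candidate
#' intersection, and (when contigs are supplied) the k-mer proto-Y contig
#' screen. Every filtering stage logs record counts in and out.
#'
#' @param inputs A [simulate_study()] object, a directory written by
#'   `simulate_study(..., dir = )`, or a named list with elements `sites`
#'   (or `vcf` path), `annotation`, `counts`, and optionally `long_reads`,
#'   `expression`, `contigs`, `female_reads`.
#' @param fs_max,qd_min,cluster_size,cluster_window Variant filter settings
#'   (see [hard_filter_variants()]).
#' @param min_reads,n_burn,n_keep,proposal_sd,likelihood ASE fit settings
#'   (see [ase_fit()]).
#' @param kmer_k,ufr_threshold k-mer screen settings.
#' @param focal_chromosome The proto-sex chromosome name.
#' @param cluster_filter_het If `TRUE` (default, matching a hard filter
#'   applied at joint genotyping) the heterozygosity summaries use the fully
#'   hard-filtered sites including the SNP-cluster stage; if `FALSE` they
#'   use only FS/QD-filtered sites, treating the cluster filter as
#'   ASE-specific.
#' @param seed Seed governing all stochastic stages.
#' @return An object of class `protoY_report` containing the stage outputs
#'   (het summaries and tests, diagnostic sites, haplotypes, `ase_fit`
#'   objects per group, contingency and Fisher results, candidate gene
#'   list with allele directions, k-mer profiles) and a stage log.
#' @examples
#' cfg <- sim_config(genes_per_chromosome = c(I = 15, III = 15),
#'                   het_site_rate = 3, seed = 4)
#' rep <- run_pipeline(simulate_study(cfg), n_keep = 500, seed = 4)
#' rep
#' @export
run_pipeline <- function(inputs,
                         fs_max = 20, qd_min = 2, cluster_size = 3,
                         cluster_window = 35,
                         min_reads = 10, n_burn = 1000, n_keep = 2000,
                         proposal_sd = 0.5,
                         likelihood = c("invariant", "identified"),
                         kmer_k = 15, ufr_threshold = 50,
                         focal_chromosome = "III",
                         cluster_filter_het = TRUE,
                         seed = 1) {
  likelihood <- match.arg(likelihood)
  if (is.character(inputs) && length(inputs) == 1 && dir.exists(inputs)) {
    inputs <- read_study_dir(inputs)
  }
  if (is.null(inputs$sites) && !is.null(inputs$vcf)) {
    inputs$sites <- read_vcf(inputs$vcf)
  }
  for (needed in c("sites", "annotation", "counts")) {
    if (is.null(inputs[[needed]])) {
      stop("pipeline input is missing '", needed, "'")
    }
  }
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, n_in = n_in,
                                          n_out = n_out)
  }

  filtered <- hard_filter_variants(inputs$sites, fs_max = fs_max,
                                   qd_min = qd_min,
                                   cluster_size = cluster_size,
                                   cluster_window = cluster_window)
  flog <- attr(filtered, "log")
  for (i in seq_len(nrow(flog))) {
    note(paste("variant filter:", flog$stage[i]), flog$n_in[i], flog$n_out[i])
  }

  het_input <- if (cluster_filter_het) {
    filtered
  } else {
    # FS/QD-filtered sites only: heterozygosity counts without the
    # SNP-cluster stage (which mainly targets ASE mapping bias)
    s <- inputs$sites
    s[(is.na(s$FS) | s$FS <= fs_max) & (is.na(s$QD) | s$QD >= qd_min), ,
      drop = FALSE]
  }
  het <- suppressMessages(gene_het_summaries(het_input, inputs$annotation))
  note("het summaries (genes)", length(unique(het_input$gene_id)), nrow(het))

  chroms <- unique(inputs$annotation$chromosome)
  het_tests <- list()
  bg <- setdiff(chroms, focal_chromosome)
  if (focal_chromosome %in% het$chromosome && length(bg) > 0 &&
      sum(het$chromosome %in% bg) >= 2) {
    het_tests$third_vs_others <-
      het_chromosome_test(het, focal_chromosome, bg)
  }
  auto <- setdiff(chroms, c(focal_chromosome, "X"))
  if ("X" %in% het$chromosome && sum(het$chromosome %in% auto) >= 2) {
    het_tests$X_vs_autosomes <- het_chromosome_test(het, "X", auto)
  }

  ase_sites <- cluster_bias_filter(filtered, cluster_size = cluster_size,
                                   cluster_window = cluster_window)
  diag_sites <- suppressMessages(find_diagnostic_sites(ase_sites))
  note("diagnostic sites", nrow(ase_sites), nrow(diag_sites))

  haplotypes <- NULL
  if (!is.null(inputs$long_reads) && nrow(diag_sites) > 0) {
    haplotypes <- phase_haplotypes(inputs$long_reads, diag_sites)
  }

  counts <- inputs$counts
  fit_g <- ase_fit(counts[counts$group == "genotypic", , drop = FALSE],
                   min_reads = min_reads, n_burn = n_burn, n_keep = n_keep,
                   seed = seed, proposal_sd = proposal_sd,
                   likelihood = likelihood)
  fit_sr <- ase_fit(counts[counts$group == "sexreversed", , drop = FALSE],
                    min_reads = min_reads, n_burn = n_burn, n_keep = n_keep,
                    seed = seed + 1, proposal_sd = proposal_sd,
                    likelihood = likelihood)
  note("ASE fit genotypic", length(unique(counts$gene_id)),
       nrow(fit_g$results))
  note("ASE fit sexreversed", length(unique(counts$gene_id)),
       nrow(fit_sr$results))

  contingency <- NULL
  fisher <- NULL
  per_chrom_fisher <- NULL
  if (nrow(fit_g$results) > 0 && nrow(fit_sr$results) > 0) {
    contingency <- suppressMessages(
      build_ase_contingency(fit_g, fit_sr, inputs$annotation,
                            focal_chromosome = focal_chromosome))
    fisher <- fisher_exact_2x2(contingency)
    per_chrom_fisher <- lapply(setNames(nm = chroms), function(ch) {
      g <- fit_g$results[fit_g$results$chromosome == ch, ]
      s <- fit_sr$results[fit_sr$results$chromosome == ch, ]
      tab <- matrix(c(sum(g$ase_class == "ASE"), sum(g$ase_class == "non-ASE"),
                      sum(s$ase_class == "ASE"), sum(s$ase_class == "non-ASE")),
                    2, 2, byrow = TRUE,
                    dimnames = list(group = c("genotypic", "sexreversed"),
                                    class = c("ASE", "non-ASE")))
      if (any(rowSums(tab) == 0)) return(NULL)
      fisher_exact_2x2(tab)
    })
    per_chrom_fisher <- Filter(Negate(is.null), per_chrom_fisher)
  }

  discordant <- character(0)
  candidates <- character(0)
  directions <- character(0)
  if (!is.null(inputs$expression)) {
    discordant <- classify_discordant(inputs$expression)
    if (!is.null(contingency)) {
      candidates <- intersect_candidates(discordant, contingency)
      if (length(candidates) > 0 && !is.null(haplotypes)) {
        directions <- vapply(candidates, function(gid) {
          hap <- haplotypes[[gid]]
          if (is.null(hap)) return("undetermined")
          prop <- fit_g$results$prop_gt_half[fit_g$results$gene_id == gid]
          assign_allele_direction(prop[1], hap, diag_sites)
        }, "")
      }
    }
    note("discordant screen", nrow(inputs$expression), length(discordant))
    note("candidate intersection", length(discordant), length(candidates))
  }

  kmer_profiles <- NULL
  if (!is.null(inputs$contigs) && !is.null(inputs$female_reads)) {
    fem <- build_kmer_set(inputs$female_reads, k = kmer_k)
    kmer_profiles <- classify_contigs(
      percent_ufr(inputs$contigs, fem, k = kmer_k),
      threshold = ufr_threshold)
    note("contig k-mer screen", length(inputs$contigs), nrow(kmer_profiles))
  }

  out <- list(het_summaries = het, het_tests = het_tests,
              diagnostic_sites = diag_sites, haplotypes = haplotypes,
              ase_genotypic = fit_g, ase_sexreversed = fit_sr,
              contingency = contingency, fisher = fisher,
              per_chromosome_fisher = per_chrom_fisher,
              discordant_genes = discordant, candidates = candidates,
              candidate_directions = directions,
              kmer_profiles = kmer_profiles,
              log = do.call(rbind, log),
              settings = list(fs_max = fs_max, qd_min = qd_min,
                              cluster_size = cluster_size,
                              cluster_window = cluster_window,
                              min_reads = min_reads, n_burn = n_burn,
                              n_keep = n_keep, likelihood = likelihood,
                              kmer_k = kmer_k,
                              ufr_threshold = ufr_threshold,
                              focal_chromosome = focal_chromosome,
                              seed = seed))
  class(out) <- "protoY_report"
  out
}

read_study_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  inputs <- list(vcf = p("variants.vcf"))
  if (file.exists(p("annotation.tsv"))) {
    inputs$annotation <- read_annotation(p("annotation.tsv"))
  }
  if (file.exists(p("allele_counts.tsv"))) {
    inputs$counts <- read_allele_counts(p("allele_counts.tsv"))
  }
  if (file.exists(p("long_reads.tsv"))) {
    inputs$long_reads <- read_long_reads(p("long_reads.tsv"))
  }
  if (file.exists(p("expression_bias.tsv"))) {
    inputs$expression <- read_tsv(p("expression_bias.tsv"))
  }
  if (file.exists(p("contigs.fasta"))) {
    inputs$contigs <- read_fasta(p("contigs.fasta"))
  }
  if (file.exists(p("female_reads.fasta"))) {
    inputs$female_reads <- read_fasta(p("female_reads.fasta"))
  }
  inputs
}

#' @export
print.protoY_report <- function(x, ...) {
  cat("Proto-Y / proto-X divergence report\n")
  cat("===================================\n\n")
  cat("Per-gene heterozygosity (pct attributable to genotypic males):\n")
  med <- tapply(x$het_summaries$pct_IIIM_het, x$het_summaries$chromosome,
                median)
  for (ch in names(med)) {
    cat(sprintf("  %-4s median %5.1f%% (%d genes)\n", ch, med[[ch]],
                sum(x$het_summaries$chromosome == ch)))
  }
  for (t in x$het_tests) {
    cat(sprintf("  %s: p = %.3g\n", t$test, t$p_value))
  }
  cat(sprintf("\nDiagnostic sites: %d\n", nrow(x$diagnostic_sites)))
  if (!is.null(x$contingency)) {
    cat("\nASE discordance between genotypes:\n")
    print(x$contingency$table)
    cat(sprintf("  Fisher's exact test: p = %.5g (odds ratio %.3g)\n",
                x$fisher$p_value, x$fisher$statistic))
  }
  if (length(x$discordant_genes) > 0 || length(x$candidates) > 0) {
    cat(sprintf("\nDiscordant sex-biased genes: %d\n",
                length(x$discordant_genes)))
    if (length(x$candidates) > 0) {
      dir <- if (length(x$candidate_directions) > 0) {
        paste0(" (", x$candidate_directions, ")")
      } else ""
      cat("Candidate proto-Y regulatory-divergence genes:\n")
      cat(paste0("  ", x$candidates, dir, collapse = "\n"), "\n")
    } else {
      cat("No candidate genes after intersection.\n")
    }
  }
  if (!is.null(x$kmer_profiles)) {
    cat(sprintf("\nContig k-mer screen (k = %d, threshold %g%%): %d candidate-Y of %d contigs\n",
                x$settings$kmer_k, x$settings$ufr_threshold,
                sum(x$kmer_profiles$label == "candidate-Y"),
                nrow(x$kmer_profiles)))
  }
  invisible(x)
}

#' Write the report tables to a directory
#'
#' Writes the heterozygosity summaries, ASE results per group, test
#' results, candidate list and k-mer profiles as TSVs.
#'
#' @param report A `protoY_report`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(report$het_summaries, file.path(dir, "het_summaries.tsv"))
  write_tsv(report$ase_genotypic$results,
            file.path(dir, "ase_genotypic.tsv"))
  write_tsv(report$ase_sexreversed$results,
            file.path(dir, "ase_sexreversed.tsv"))
  tests <- c(report$het_tests,
             if (!is.null(report$fisher)) list(contingency = report$fisher),
             report$per_chromosome_fisher)
  if (length(tests) > 0) {
    write_tsv(data.frame(test = vapply(tests, `[[`, "", "test"),
                         statistic = vapply(tests, `[[`, 0, "statistic"),
                         p_value = vapply(tests, `[[`, 0, "p_value")),
              file.path(dir, "tests.tsv"))
  }
  writeLines(report$candidates, file.path(dir, "candidates.txt"))
  if (!is.null(report$kmer_profiles)) {
    write_tsv(report$kmer_profiles, file.path(dir, "kmer_profiles.tsv"))
  }
  if (!is.null(report$log)) write_tsv(report$log, file.path(dir, "log.tsv"))
  invisible(dir)
}
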