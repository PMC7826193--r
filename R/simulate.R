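BASES <- c("A", "C", "G", "T")

# Genes are laid out on a fixed grid of candidate variant "slots" spaced 72 bp
# apart, with <= 11 bp of jitter within a slot. Any two sites in different
# slots are therefore > 34 bp apart, so the only 3-SNP/35-bp clusters in the
# simulation are the planted artifact clusters (3 SNPs at +0/+12/+24 within
# one slot). This keeps the truth labels of the cluster filter exact.
SLOT_SPACING <- 72L
SLOT_JITTER <- 11L

gene_layout <- function(cfg) {
  n_slots <- max(20L, as.integer(ceiling(2.5 * cfg$het_site_rate + 8)))
  gene_length <- SLOT_SPACING * n_slots
  list(n_slots = n_slots, gene_length = gene_length,
       gene_spacing = gene_length + 600L)
}

gene_table <- function(cfg) {
  lay <- gene_layout(cfg)
  chroms <- names(cfg$genes_per_chromosome)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    n <- cfg$genes_per_chromosome[[ch]]
    if (n == 0) return(NULL)
    i <- seq_len(n)
    start <- (i - 1L) * lay$gene_spacing + 1L
    data.frame(gene_id = sprintf("%s_g%04d", ch, i), chromosome = ch,
               start = start, end = start + lay$gene_length - 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

paste_gt <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "/"), paste(b, a, sep = "/"))
}

#' Simulate jointly genotyped variant sites with ground truth
#'
#' Generates per-site genotype calls for the two genotype groups. Background
#' heterozygosity is group-symmetric; for divergent third-chromosome genes
#' (a `frac_div_genes_III` fraction, genotypic group only) extra sites are
#' planted that are heterozygous in genotypic males and homozygous in
#' sex-reversed males. A `cluster_artifact_rate` fraction of genes carries a
#' planted 3-SNP cluster within 35 bp, flagged in the truth table.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `sites` (variant table: chromosome, position,
#'   ref, alt, variant_class, gene_id, gt_G, gt_SR, FS, QD), `annotation`
#'   (gene -> chromosome/start/end), and `truth` (list of `genes` and `sites`
#'   data frames carrying planted allele fractions, divergence flags,
#'   proto-X/proto-Y allele assignments and artifact labels).
#' @examples
#' sim <- simulate_variants(sim_config(
#'   genes_per_chromosome = c(I = 5, III = 5), seed = 1))
#' head(sim$sites)
#' @export
simulate_variants <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(stream_seed(cfg$seed, 1L), {
    genes <- gene_table(cfg)
    lay <- gene_layout(cfg)
    r <- cfg$het_site_rate
    ng <- nrow(genes)

    iii <- which(genes$chromosome == "III")
    n_div <- round(cfg$frac_div_genes_III * length(iii))
    div_idx <- if (n_div > 0) sort(sample(iii, n_div)) else integer(0)
    genes$divergent <- seq_len(ng) %in% div_idx

    # per-gene site counts by class
    n_gdiag <- rpois(ng, 2 * r / 3) +
      ifelse(genes$divergent, 1 + rpois(ng, 2 * r / 3), 0L)
    n_sronly <- rpois(ng, 2 * r / 3)
    n_both <- rpois(ng, r / 3)
    n_fixed <- rpois(ng, r / 6)
    artifact <- runif(ng) < cfg$cluster_artifact_rate

    # trim low-information classes first if a gene's slot grid is full
    avail <- lay$n_slots - as.integer(artifact)
    over <- pmax(n_gdiag + n_sronly + n_both + n_fixed - avail, 0L)
    take <- pmin(over, n_fixed); n_fixed <- n_fixed - take; over <- over - take
    take <- pmin(over, n_both); n_both <- n_both - take; over <- over - take
    take <- pmin(over, n_sronly); n_sronly <- n_sronly - take; over <- over - take
    n_gdiag <- n_gdiag - over

    # shuffle each gene's slots once; the artifact (if any) takes the first
    # shuffled slot, ordinary sites take the following ones
    shuffled <- matrix(0L, lay$n_slots, ng)
    for (gi in seq_len(ng)) shuffled[, gi] <- sample.int(lay$n_slots)
    m <- n_gdiag + n_sronly + n_both + n_fixed

    gidx_c <- c(rep(seq_len(ng), n_gdiag), rep(seq_len(ng), n_sronly),
                rep(seq_len(ng), n_both), rep(seq_len(ng), n_fixed))
    cls_c <- rep(c("gdiag", "sronly", "both", "fixed"),
                 c(sum(n_gdiag), sum(n_sronly), sum(n_both), sum(n_fixed)))
    ord0 <- order(gidx_c)
    gidx <- gidx_c[ord0]
    cls <- cls_c[ord0]
    offset <- (gidx - 1L) * lay$n_slots + as.integer(artifact)[gidx]
    slots <- shuffled[offset + sequence(m)]
    pos <- genes$start[gidx] + (slots - 1L) * SLOT_SPACING +
      sample(0:SLOT_JITTER, length(gidx), replace = TRUE)

    art_g <- which(artifact)
    gidx <- c(gidx, rep(art_g, each = 3L))
    cls <- c(cls, rep("artifact", 3L * length(art_g)))
    pos <- c(pos, rep(genes$start[art_g] +
                        (shuffled[(art_g - 1L) * lay$n_slots + 1L] - 1L) *
                        SLOT_SPACING, each = 3L) + c(0L, 12L, 24L))

    n_sites <- length(pos)
    others <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                    c("A", "C", "T"), c("A", "C", "G"))
    ref <- sample(BASES, n_sites, replace = TRUE)
    alt <- others[cbind(match(ref, BASES), sample.int(3L, n_sites, TRUE))]
    variant_class <- rep("SNP", n_sites)
    is_indel <- cls %in% c("sronly", "both") & runif(n_sites) < cfg$indel_rate
    alt[is_indel] <- paste0(ref[is_indel],
                            sample(BASES, sum(is_indel), replace = TRUE))
    variant_class[is_indel] <- "indel"

    het <- paste_gt(ref, alt)
    hom_ref <- paste_gt(ref, ref)
    hom_alt <- paste_gt(alt, alt)
    coin <- runif(n_sites) < 0.5
    gt_G <- gt_SR <- character(n_sites)
    III_allele <- IIIM_allele <- rep(NA_character_, n_sites)
    i <- cls == "gdiag"
    gt_G[i] <- het[i]
    gt_SR[i] <- ifelse(coin[i], hom_ref[i], hom_alt[i])
    III_allele[i] <- ifelse(coin[i], ref[i], alt[i])
    IIIM_allele[i] <- ifelse(coin[i], alt[i], ref[i])
    i <- cls == "sronly"
    gt_SR[i] <- het[i]
    gt_G[i] <- ifelse(coin[i], hom_ref[i], hom_alt[i])
    i <- cls %in% c("both", "artifact")
    gt_G[i] <- het[i]
    gt_SR[i] <- het[i]
    i <- cls == "fixed"
    gt_G[i] <- hom_alt[i]
    gt_SR[i] <- hom_alt[i]

    FS <- round(runif(n_sites, 0, 15), 3)
    QD <- round(runif(n_sites, 5, 30), 3)
    fs_fail <- runif(n_sites) < cfg$fs_fail_rate
    qd_fail <- runif(n_sites) < cfg$qd_fail_rate
    FS[fs_fail] <- round(runif(sum(fs_fail), 20.01, 60), 3)
    QD[qd_fail] <- round(runif(sum(qd_fail), 0, 1.99), 3)

    all_sites <- data.frame(
      chromosome = genes$chromosome[gidx], position = pos, ref = ref,
      alt = alt, variant_class = variant_class,
      gene_id = genes$gene_id[gidx], gt_G = gt_G, gt_SR = gt_SR,
      FS = FS, QD = QD, site_class = cls,
      III_allele = III_allele, IIIM_allele = IIIM_allele,
      stringsAsFactors = FALSE)
    chrom_order <- names(cfg$genes_per_chromosome)
    all_sites <- all_sites[order(match(all_sites$chromosome, chrom_order),
                                 all_sites$position), ]
    rownames(all_sites) <- NULL

    # gene truth: orientation of the canonical focal haplotype is taken from
    # the first (lowest-position) diagnostic site
    dsub <- all_sites[all_sites$site_class == "gdiag", , drop = FALSE]
    first <- dsub[!duplicated(dsub$gene_id), , drop = FALSE]
    fi <- match(genes$gene_id, first$gene_id)
    focal_is_IIIM <- first$IIIM_allele[fi] < first$III_allele[fi]
    n_diag <- integer(ng)
    tab <- table(dsub$gene_id)
    n_diag[match(names(tab), genes$gene_id)] <- as.integer(tab)
    rho_IIIM_G <- ifelse(genes$divergent, cfg$planted_rho, 0.5)
    truth_genes <- data.frame(
      gene_id = genes$gene_id, chromosome = genes$chromosome,
      divergent = genes$divergent, n_diagnostic = n_diag,
      focal_is_IIIM = focal_is_IIIM, rho_IIIM_G = rho_IIIM_G,
      rho_focal_G = ifelse(focal_is_IIIM, rho_IIIM_G, 1 - rho_IIIM_G),
      rho_focal_SR = ifelse(is.na(focal_is_IIIM), NA_real_, 0.5),
      stringsAsFactors = FALSE)

    truth_sites <- data.frame(
      chromosome = all_sites$chromosome, position = all_sites$position,
      gene_id = all_sites$gene_id,
      het_G = grepl("/", all_sites$gt_G) &
        !vapply(strsplit(all_sites$gt_G, "/", fixed = TRUE),
                function(x) x[1] == x[2], TRUE),
      het_SR = !vapply(strsplit(all_sites$gt_SR, "/", fixed = TRUE),
                       function(x) x[1] == x[2], TRUE),
      is_diagnostic = all_sites$site_class == "gdiag",
      III_allele = all_sites$III_allele,
      IIIM_allele = all_sites$IIIM_allele,
      cluster_artifact = all_sites$site_class == "artifact",
      stringsAsFactors = FALSE)

    sites <- all_sites[, c("chromosome", "position", "ref", "alt",
                           "variant_class", "gene_id", "gt_G", "gt_SR",
                           "FS", "QD")]
    list(sites = sites,
         annotation = genes[, c("gene_id", "chromosome", "start", "end")],
         truth = list(genes = truth_genes, sites = truth_sites))
  })
}

#' Simulate per-gene, per-replicate allele-specific read counts
#'
#' For every gene with at least one diagnostic site, draws per-replicate
#' totals from a Poisson with mean `depth_mean`, and focal-haplotype counts
#' from a binomial (or beta-binomial when `dispersion > 0`) around the gene's
#' true focal allele fraction: `planted_rho` (re-oriented to the canonical
#' focal haplotype) for divergent genes in the genotypic group, 0.5
#' otherwise.
#'
#' @param config A [sim_config()] object.
#' @param truth The `truth` element returned by [simulate_variants()].
#' @return A data frame with columns gene_id, chromosome, group, replicate,
#'   focal_count, total_count.
#' @export
simulate_allele_counts <- function(config, truth) {
  validate_sim_config(config)
  cfg <- config
  with_seed(stream_seed(cfg$seed, 2L), {
    g <- truth$genes[truth$genes$n_diagnostic > 0, , drop = FALSE]
    if (nrow(g) == 0) {
      return(data.frame(gene_id = character(), chromosome = character(),
                        group = character(), replicate = integer(),
                        focal_count = integer(), total_count = integer(),
                        stringsAsFactors = FALSE))
    }
    reps <- seq_len(cfg$n_replicates)
    grid <- expand.grid(replicate = reps,
                        group = c("genotypic", "sexreversed"),
                        idx = seq_len(nrow(g)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rho <- ifelse(grid$group == "genotypic", g$rho_focal_G[grid$idx],
                  g$rho_focal_SR[grid$idx])
    total <- rpois(nrow(grid), cfg$depth_mean)
    p <- rho
    if (cfg$dispersion > 0) {
      s <- (1 - cfg$dispersion) / cfg$dispersion
      p <- rbeta(nrow(grid), rho * s, (1 - rho) * s)
    }
    focal <- rbinom(nrow(grid), total, p)
    out <- data.frame(gene_id = g$gene_id[grid$idx],
                      chromosome = g$chromosome[grid$idx],
                      group = grid$group, replicate = grid$replicate,
                      focal_count = focal, total_count = total,
                      stringsAsFactors = FALSE)
    out <- out[order(match(out$gene_id, g$gene_id), out$group, out$replicate), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate long-read allele observations for phasing
#'
#' Each read samples one of the gene's two true haplotypes (equal
#' probability, as for genomic DNA), covers a contiguous run of the gene's
#' diagnostic sites, and reports the haplotype allele at each covered site
#' flipped independently with probability `long_read_error`.
#'
#' @inheritParams simulate_allele_counts
#' @return A data frame with one row per read-site observation: read_id,
#'   gene_id, position, allele.
#' @export
simulate_long_reads <- function(config, truth) {
  validate_sim_config(config)
  cfg <- config
  with_seed(stream_seed(cfg$seed, 3L), {
    ts <- truth$sites[truth$sites$is_diagnostic, , drop = FALSE]
    gids <- unique(ts$gene_id)
    acc <- vector("list", length(gids))
    for (i in seq_along(gids)) {
      gs <- ts[ts$gene_id == gids[i], , drop = FALSE]
      gs <- gs[order(gs$position), , drop = FALSE]
      k <- nrow(gs)
      tg <- truth$genes[truth$genes$gene_id == gids[i], ]
      hap_focal <- if (isTRUE(tg$focal_is_IIIM)) gs$IIIM_allele else gs$III_allele
      hap_other <- if (isTRUE(tg$focal_is_IIIM)) gs$III_allele else gs$IIIM_allele
      d <- cfg$long_read_depth
      if (d == 0) next
      # half the reads span the whole gene (long-read regime); the rest
      # cover a random contiguous sub-window
      full <- runif(d) < 0.5
      a <- sample.int(k, d, replace = TRUE)
      b <- sample.int(k, d, replace = TRUE)
      start <- ifelse(full, 1L, pmin(a, b))
      stop <- ifelse(full, k, pmax(a, b))
      hap_is_focal <- runif(d) < 0.5
      rows <- vector("list", d)
      for (rd in seq_len(d)) {
        idx <- start[rd]:stop[rd]
        hap <- if (hap_is_focal[rd]) hap_focal[idx] else hap_other[idx]
        oth <- if (hap_is_focal[rd]) hap_other[idx] else hap_focal[idx]
        flip <- runif(length(idx)) < cfg$long_read_error
        hap[flip] <- oth[flip]
        rows[[rd]] <- data.frame(
          read_id = sprintf("%s_r%03d", gids[i], rd), gene_id = gids[i],
          position = gs$position[idx], allele = hap,
          stringsAsFactors = FALSE)
      }
      acc[[i]] <- do.call(rbind, rows)
    }
    out <- do.call(rbind, acc)
    if (is.null(out)) {
      out <- data.frame(read_id = character(), gene_id = character(),
                        position = integer(), allele = character(),
                        stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Simulate assembly contigs and a female read set for the k-mer screen
#'
#' Shared contigs are substrings of a simulated female genome whose k-mers
#' are fully covered by the female read set (reads tile the genome with
#' k-1 bp overlap); male-specific contigs are novel sequence sharing no
#' canonical k-mer with the female reads; mixed contigs are half shared,
#' half novel, sized so that exactly half of their distinct k-mers are
#' unmatched.
#'
#' @param config A [sim_config()] object.
#' @return A list with `contigs` (named character vector), `female_reads`
#'   (character vector) and `truth` (contig_id, class in
#'   shared/male-specific/mixed).
#' @export
simulate_contigs <- function(config) {
  validate_sim_config(config)
  cfg <- config
  k <- as.integer(cfg$kmer_k)
  with_seed(stream_seed(cfg$seed, 4L), {
    genome <- random_dna(cfg$female_genome_length)
    rl <- cfg$female_read_length
    starts <- seq(1L, cfg$female_genome_length - rl + 1L, by = rl - (k - 1L))
    if (starts[length(starts)] < cfg$female_genome_length - rl + 1L) {
      starts <- c(starts, cfg$female_genome_length - rl + 1L)
    }
    reads <- substring(genome, starts, starts + rl - 1L)
    female_set <- build_kmer_set(reads, k)

    novel_dna <- function(n) {
      # resample until no canonical k-mer collides with the female set
      for (i in 1:50) {
        s <- random_dna(n)
        if (!any(canonical_kmers(s, k) %in% female_set)) return(s)
      }
      stop("could not generate male-specific sequence free of female k-mers")
    }

    contigs <- character(0)
    truth <- data.frame(contig_id = character(), class = character(),
                        stringsAsFactors = FALSE)
    cl <- as.integer(cfg$contig_length)
    add <- function(id, seq, class) {
      contigs[[id]] <<- seq
      truth <<- rbind(truth, data.frame(contig_id = id, class = class,
                                        stringsAsFactors = FALSE))
    }
    for (i in seq_len(cfg$n_shared_contigs)) {
      at <- sample.int(cfg$female_genome_length - cl + 1L, 1)
      add(sprintf("contig_shared_%02d", i), substring(genome, at, at + cl - 1L),
          "shared")
    }
    for (i in seq_len(cfg$n_male_contigs)) {
      add(sprintf("contig_male_%02d", i), novel_dna(cl), "male-specific")
    }
    # shared part longer by k-1 so unmatched k-mers (novel + junction) are
    # exactly half of the distinct total
    ls <- (cl + k - 1L) %/% 2L
    ln <- cl - ls
    for (i in seq_len(cfg$n_mixed_contigs)) {
      at <- sample.int(cfg$female_genome_length - ls + 1L, 1)
      add(sprintf("contig_mixed_%02d", i),
          paste0(substring(genome, at, at + ls - 1L), novel_dna(ln)), "mixed")
    }
    list(contigs = contigs, female_reads = reads, truth = truth)
  })
}

#' Simulate sex-biased expression direction labels
#'
#' Assigns each gene a three-level expression bias label (vs phenotypic
#' females) in each male genotype. Labels are concordant between genotypes
#' except for the planted candidate: when `plant_discordant` is set and
#' divergent genes exist, the first divergent third-chromosome gene is
#' male-biased in genotypic males and female-biased in sex-reversed males.
#'
#' @inheritParams simulate_allele_counts
#' @return A data frame gene_id, chromosome, bias_genotypic,
#'   bias_sexreversed, with the candidate gene id in attribute
#'   `"candidate"` (NA if none).
#' @export
simulate_expression_labels <- function(config, truth) {
  validate_sim_config(config)
  cfg <- config
  with_seed(stream_seed(cfg$seed, 5L), {
    g <- truth$genes
    lab <- sample(c("unbiased", "male-biased", "female-biased"), nrow(g),
                  replace = TRUE, prob = c(0.6, 0.2, 0.2))
    out <- data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
                      bias_genotypic = lab, bias_sexreversed = lab,
                      stringsAsFactors = FALSE)
    candidate <- NA_character_
    div_iii <- which(g$divergent & g$chromosome == "III" & g$n_diagnostic > 0)
    if (cfg$plant_discordant && length(div_iii) > 0) {
      candidate <- g$gene_id[div_iii[1]]
      out$bias_genotypic[div_iii[1]] <- "male-biased"
      out$bias_sexreversed[div_iii[1]] <- "female-biased"
    }
    attr(out, "candidate") <- candidate
    out
  })
}

#' Generate a complete synthetic study
#'
#' Runs all simulation stages from one seed and optionally writes every
#' pipeline input to `dir` in its on-disk format (VCF, TSVs, FASTA, JSON
#' truth).
#'
#' @param config A [sim_config()] object.
#' @param dir Optional output directory; created if missing.
#' @return A list with the in-memory inputs (`sites`, `annotation`, `counts`,
#'   `long_reads`, `expression`, `contigs`, `female_reads`), the ground
#'   `truth`, and (when `dir` is given) a `paths` element naming the files
#'   written.
#' @examples
#' study <- simulate_study(sim_config(
#'   genes_per_chromosome = c(I = 10, III = 10), seed = 2))
#' names(study)
#' @export
simulate_study <- function(config, dir = NULL) {
  validate_sim_config(config)
  sim <- simulate_variants(config)
  counts <- simulate_allele_counts(config, sim$truth)
  long_reads <- simulate_long_reads(config, sim$truth)
  contig_sim <- simulate_contigs(config)
  expression <- simulate_expression_labels(config, sim$truth)

  truth <- sim$truth
  truth$contigs <- contig_sim$truth
  truth$candidate <- attr(expression, "candidate")

  study <- list(sites = sim$sites, annotation = sim$annotation,
                counts = counts, long_reads = long_reads,
                expression = expression, contigs = contig_sim$contigs,
                female_reads = contig_sim$female_reads, truth = truth,
                config = config)
  class(study) <- "proto_study"

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      vcf = file.path(dir, "variants.vcf"),
      annotation = file.path(dir, "annotation.tsv"),
      counts = file.path(dir, "allele_counts.tsv"),
      long_reads = file.path(dir, "long_reads.tsv"),
      expression = file.path(dir, "expression_bias.tsv"),
      contigs = file.path(dir, "contigs.fasta"),
      female_reads = file.path(dir, "female_reads.fasta"),
      truth = file.path(dir, "truth.json"))
    write_variants_vcf(sim$sites, paths$vcf)
    write_tsv(sim$annotation, paths$annotation)
    write_tsv(counts, paths$counts)
    write_long_reads(long_reads, paths$long_reads)
    write_tsv(expression, paths$expression)
    write_fasta(contig_sim$contigs, paths$contigs)
    write_fasta(setNames(contig_sim$female_reads,
                         sprintf("female_read_%04d",
                                 seq_along(contig_sim$female_reads))),
                paths$female_reads)
    jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                         na = "null", auto_unbox = TRUE, digits = NA)
    study$paths <- paths
  }
  study
}
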