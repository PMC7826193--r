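check_sorted <- function(sites) {
  if (nrow(sites) < 2) return(invisible(TRUE))
  runs <- rle(sites$chromosome)$values
  if (anyDuplicated(runs) > 0) {
    stop("sites must be sorted by (chromosome, position); ",
         "chromosome blocks are interleaved -- sort the input first",
         call. = FALSE)
  }
  ok <- tapply(sites$position, sites$chromosome,
               function(p) !is.unsorted(p))
  if (!all(ok)) {
    stop("sites must be sorted by (chromosome, position); ",
         "positions are unsorted -- sort the input first", call. = FALSE)
  }
  invisible(TRUE)
}

is_het <- function(gt) {
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(x) length(x) == 2 && x[1] != x[2], TRUE)
}

# Indices of SNPs belonging to any run of >= cluster_size SNPs spanning
# <= window bp (both endpoints inclusive, i.e. max - min <= window - 1),
# computed per chromosome on sorted positions.
snp_cluster_members <- function(chromosome, position, is_snp,
                                cluster_size = 3, window = 35) {
  clustered <- logical(length(position))
  for (ch in unique(chromosome)) {
    sel <- which(chromosome == ch & is_snp)
    p <- position[sel]
    n <- length(p)
    if (n < cluster_size) next
    for (i in seq_len(n - cluster_size + 1)) {
      j <- i + cluster_size - 1
      if (p[j] - p[i] <= window - 1) clustered[sel[i:j]] <- TRUE
    }
  }
  clustered
}

#' Hard-filter variant sites
#'
#' Applies the quality filters used after joint genotyping: sites with
#' Fisher-strand `FS > 20` or quality-by-depth `QD < 2` are removed (strict
#' inequalities), then every SNP that is one of three or more SNPs within a
#' 35 bp window is removed. Indels are never cluster-filtered. Sites with
#' missing FS or QD pass those filters with a warning.
#'
#' @param sites Variant table sorted by (chromosome, position), with columns
#'   `chromosome`, `position`, `variant_class`, `FS`, `QD`.
#' @param fs_max FS threshold; sites with `FS > fs_max` are removed.
#' @param qd_min QD threshold; sites with `QD < qd_min` are removed.
#' @param cluster_size,cluster_window SNP-cluster filter parameters: remove
#'   SNPs in any set of `cluster_size` SNPs spanning `cluster_window` bp
#'   (endpoints inclusive).
#' @return The retained subset of `sites`, order preserved, with attribute
#'   `"log"` recording counts in/out per stage.
#' @examples
#' s <- data.frame(chromosome = "III", position = c(100, 110, 134, 500),
#'                 variant_class = "SNP", FS = 1, QD = 10)
#' hard_filter_variants(s)  # the 3-SNP cluster at 100-134 is removed
#' @export
hard_filter_variants <- function(sites, fs_max = 20, qd_min = 2,
                                 cluster_size = 3, cluster_window = 35) {
  check_sorted(sites)
  n0 <- nrow(sites)
  if (anyNA(sites$FS) || anyNA(sites$QD)) {
    warning("sites with missing FS or QD pass those filters")
  }
  keep_q <- (is.na(sites$FS) | sites$FS <= fs_max) &
    (is.na(sites$QD) | sites$QD >= qd_min)
  q <- sites[keep_q, , drop = FALSE]
  out <- cluster_bias_filter(q, cluster_size = cluster_size,
                             cluster_window = cluster_window)
  log <- rbind(data.frame(stage = "FS/QD", n_in = n0, n_out = nrow(q)),
               attr(out, "log"))
  attr(out, "log") <- log
  out
}

#' Remove SNP clusters (mapping-bias filter)
#'
#' Removes every SNP belonging to a set of `cluster_size` or more SNPs whose
#' positions span at most `cluster_window` bp (both endpoints counted). This
#' is the cluster stage of [hard_filter_variants()], exposed separately
#' because it is also applied on its own to reduce reference-mapping bias in
#' allele-specific expression estimation. Idempotent; indels are untouched.
#'
#' @inheritParams hard_filter_variants
#' @return The retained subset of `sites`, order preserved, with a `"log"`
#'   attribute.
#' @export
cluster_bias_filter <- function(sites, cluster_size = 3, cluster_window = 35) {
  check_sorted(sites)
  n0 <- nrow(sites)
  clustered <- snp_cluster_members(sites$chromosome, sites$position,
                                   sites$variant_class == "SNP",
                                   cluster_size, cluster_window)
  out <- sites[!clustered, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- data.frame(stage = "SNP cluster", n_in = n0,
                                 n_out = nrow(out))
  out
}

assign_genes <- function(sites, annotation) {
  gid <- sites$gene_id
  if (is.null(gid)) gid <- rep(NA_character_, nrow(sites))
  miss <- which(is.na(gid))
  if (length(miss) > 0 && !is.null(annotation)) {
    for (i in miss) {
      hit <- annotation$chromosome == sites$chromosome[i] &
        annotation$start <= sites$position[i] &
        annotation$end >= sites$position[i]
      if (any(hit)) gid[i] <- annotation$gene_id[which(hit)[1]]
    }
  }
  gid
}

#' Per-gene relative heterozygosity summaries
#'
#' Counts, for each gene, the sites heterozygous in the genotypic group
#' (`h_G`) and in the sex-reversed group (`h_SR`) -- a site heterozygous in
#' both groups counts toward both -- and computes the percent of
#' heterozygous sites attributable to the genotypic males,
#' `100 * h_G / (h_G + h_SR)`: 0 if heterozygous sites occur only in
#' sex-reversed males, 100 if only in genotypic males, 50 if equally many in
#' both. Genes with no heterozygous site in either group are excluded.
#'
#' @param sites Filtered variant table with `gt_G`, `gt_SR` genotype columns
#'   (unordered allele pairs, e.g. `"A/G"`).
#' @param annotation Optional gene annotation (gene_id, chromosome, start,
#'   end, 1-based inclusive) used to assign sites lacking a `gene_id`.
#' @return A data frame gene_id, chromosome, h_G, h_SR, pct_IIIM_het.
#' @examples
#' s <- data.frame(chromosome = "III", position = c(10, 20, 30),
#'                 gene_id = "g1", gt_G = c("A/G", "A/G", "C/C"),
#'                 gt_SR = c("A/A", "A/G", "C/T"))
#' gene_het_summaries(s)  # h_G = 2, h_SR = 2 -> 50%
#' @export
gene_het_summaries <- function(sites, annotation = NULL) {
  gid <- assign_genes(sites, annotation)
  keep <- !is.na(gid)
  sites <- sites[keep, , drop = FALSE]
  gid <- gid[keep]
  het_g <- is_het(sites$gt_G)
  het_sr <- is_het(sites$gt_SR)
  hg <- tapply(het_g, gid, sum)
  hsr <- tapply(het_sr, gid, sum)
  chrom <- tapply(sites$chromosome, gid, function(x) x[1])
  out <- data.frame(gene_id = names(hg), chromosome = as.character(chrom),
                    h_G = as.integer(hg), h_SR = as.integer(hsr),
                    stringsAsFactors = FALSE)
  excluded <- out$h_G + out$h_SR == 0
  if (any(excluded)) {
    message(sum(excluded),
            " gene(s) with no heterozygous site in either group excluded")
    out <- out[!excluded, , drop = FALSE]
  }
  out$pct_IIIM_het <- 100 * out$h_G / (out$h_G + out$h_SR)
  rownames(out) <- NULL
  out
}

#' Identify diagnostic sites and assign proto-X / proto-Y alleles
#'
#' A diagnostic site is heterozygous in genotypic males and homozygous in
#' sex-reversed males. The allele shared with the sex-reversed homozygote is
#' assigned to the standard third chromosome (III, proto-X); the allele
#' unique to genotypic males is assigned to the male-determining third
#' chromosome (III^M, proto-Y). Sites heterozygous in both groups carry the
#' same genotype in both and are removed; heterozygotes sharing no allele
#' with the sex-reversed homozygote (triallelic conflicts) are excluded with
#' a message.
#'
#' @param sites Filtered variant table with `gt_G`, `gt_SR` and `gene_id`.
#' @return A data frame chromosome, position, gene_id, III_allele,
#'   IIIM_allele.
#' @examples
#' s <- data.frame(chromosome = "III", position = 7, gene_id = "g1",
#'                 gt_G = "A/G", gt_SR = "A/A")
#' find_diagnostic_sites(s)  # III allele A, III^M allele G
#' @export
find_diagnostic_sites <- function(sites) {
  het_g <- is_het(sites$gt_G)
  het_sr <- is_het(sites$gt_SR)
  cand <- which(het_g & !het_sr)
  if (length(cand) == 0) {
    return(data.frame(chromosome = character(), position = integer(),
                      gene_id = character(), III_allele = character(),
                      IIIM_allele = character(), stringsAsFactors = FALSE))
  }
  g_alleles <- strsplit(sites$gt_G[cand], "/", fixed = TRUE)
  sr_allele <- vapply(strsplit(sites$gt_SR[cand], "/", fixed = TRUE),
                      `[`, "", 1)
  shared <- mapply(function(g, s) s %in% g, g_alleles, sr_allele)
  if (any(!shared)) {
    message(sum(!shared),
            " triallelic site(s) excluded: genotypic heterozygote shares no ",
            "allele with the sex-reversed homozygote")
  }
  cand <- cand[shared]
  g_alleles <- g_alleles[shared]
  sr_allele <- sr_allele[shared]
  iiim <- mapply(function(g, s) setdiff(g, s)[1], g_alleles, sr_allele)
  out <- data.frame(chromosome = sites$chromosome[cand],
                    position = sites$position[cand],
                    gene_id = if (is.null(sites$gene_id)) NA_character_ else
                      sites$gene_id[cand],
                    III_allele = as.character(sr_allele),
                    IIIM_allele = as.character(iiim),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
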