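ASE_BINS <- c("extreme-low", "moderate-low", "non-ASE", "moderate-high",
              "extreme-high")

# core sampler: pooled counts in, kept rho draws out
rho_core <- function(focal, total, n_burn, n_keep, proposal_sd, symmetrize) {
  f <- sum(focal)
  t <- sum(total)
  if (t < 1) {
    stop("zero total reads: gene/group should have been removed by ",
         "min_read_filter", call. = FALSE)
  }
  if (f < 0 || f > t) stop("focal counts must satisfy 0 <= focal <= total")
  p0 <- (f + 0.5) / (t + 1)
  res <- rho_metropolis(f, t, as.integer(n_burn), as.integer(n_keep),
                        proposal_sd, symmetrize, log(p0 / (1 - p0)))
  kept <- res$kept
  q <- max(1L, floor(length(kept) / 4))
  gap <- abs(mean(kept[seq_len(q)]) - mean(kept[seq(length(kept) - q + 1,
                                                    length(kept))]))
  list(kept = kept, prop_gt_half = mean(kept > 0.5),
       accept_rate = res$accept_rate, geweke_gap = gap,
       converged = gap <= 0.1)
}

#' Sample the per-gene allele fraction by MCMC
#'
#' Random-walk Metropolis on the logit of the focal-haplotype expression
#' fraction rho, with a uniform prior and a binomial likelihood for the
#' per-replicate focal/total read counts (which share one rho, so the pooled
#' counts are sufficient). A 1,000-iteration burn-in is discarded and at
#' least 500 further draws are kept; the per-gene ASE statistic is the
#' proportion of kept iterations with rho > 0.5.
#'
#' Two likelihoods are available. `"invariant"` (the default, used for ASE
#' classification) averages the likelihood over the two labelings of the
#' focal haplotype, making the target invariant under `rho <-> 1 - rho`:
#' because which haplotype is called "focal" is arbitrary, a balanced gene
#' mixes across 0.5 and its statistic concentrates near 0.5, while a
#' strongly skewed gene stays in the data-supported mode and yields a
#' statistic near 0 or 1. `"identified"` is the plain binomial likelihood,
#' appropriate when the focal haplotype is externally fixed; its posterior
#' is the closed-form Beta(f+1, t-f+1).
#'
#' @param focal,total Per-replicate focal and total read counts (equal
#'   length; pooled internally).
#' @param n_burn,n_keep Burn-in and kept iterations (`n_keep >= 500`).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param proposal_sd Random-walk proposal standard deviation on the logit
#'   scale.
#' @param likelihood `"invariant"` or `"identified"` (see Details).
#' @param gene_id,group Optional labels stored in the result.
#' @return An object of class `rho_trace`: kept samples, `prop_gt_half`,
#'   acceptance rate, and a convergence flag (first-quarter vs last-quarter
#'   mean gap of the kept draws <= 0.1). A warning is raised when the gap
#'   exceeds 0.1.
#' @examples
#' tr <- sample_rho(c(20, 15, 15), c(25, 20, 20), seed = 1)
#' tr$prop_gt_half
#' @export
sample_rho <- function(focal, total, n_burn = 1000, n_keep = 500,
                       seed = NULL, proposal_sd = 0.5,
                       likelihood = c("invariant", "identified"),
                       gene_id = NA_character_, group = NA_character_) {
  likelihood <- match.arg(likelihood)
  if (length(focal) != length(total)) {
    stop("focal and total must have the same length")
  }
  if (n_keep < 500) stop("n_keep must be at least 500")
  res <- with_seed(seed,
                   rho_core(focal, total, n_burn, n_keep, proposal_sd,
                            likelihood == "invariant"))
  if (!res$converged) {
    warning(sprintf("rho chain may not have converged (segment mean gap %.3f > 0.1)",
                    res$geweke_gap))
  }
  out <- list(gene_id = gene_id, group = group, kept_samples = res$kept,
              n_burn = n_burn, n_keep = n_keep, seed = seed,
              likelihood = likelihood, proposal_sd = proposal_sd,
              prop_gt_half = res$prop_gt_half,
              accept_rate = res$accept_rate, geweke_gap = res$geweke_gap,
              converged = res$converged,
              focal_reads = sum(focal), total_reads = sum(total))
  class(out) <- "rho_trace"
  out
}

#' @export
print.rho_trace <- function(x, ...) {
  cat(sprintf("rho trace%s%s: %d kept draws (%s likelihood)\n",
              if (is.na(x$gene_id)) "" else paste0(" for ", x$gene_id),
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$kept_samples), x$likelihood))
  cat(sprintf("  pooled counts %d/%d; prop(rho > 0.5) = %.3f; accept %.2f%s\n",
              x$focal_reads, x$total_reads, x$prop_gt_half, x$accept_rate,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' Minimum pooled read-count filter
#'
#' Retains gene/group combinations with at least `threshold` reads pooled
#' across the group's replicates (default ten reads over the three RNA-seq
#' libraries).
#'
#' @param counts Allele count table (gene_id, group, replicate, focal_count,
#'   total_count).
#' @param threshold Minimum pooled total count.
#' @return A data frame gene_id, group, focal_reads, total_reads, retained.
#' @export
min_read_filter <- function(counts, threshold = 10) {
  key <- interaction(counts$gene_id, counts$group, drop = TRUE)
  tot <- tapply(counts$total_count, key, sum)
  foc <- tapply(counts$focal_count, key, sum)
  parts <- strsplit(names(tot), ".", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 1),
    group = vapply(parts, `[`, "", 2),
    focal_reads = as.integer(foc), total_reads = as.integer(tot),
    stringsAsFactors = FALSE)
  out$retained <- out$total_reads >= threshold
  rownames(out) <- NULL
  out[order(out$gene_id, out$group), ]
}

#' Classify a gene's ASE statistic into the five bins
#'
#' Bins the proportion of MCMC iterations with rho > 0.5 into extreme-low
#' `[0, 0.125)`, moderate-low `[0.125, 0.375)`, non-ASE `[0.375, 0.625]`,
#' moderate-high `(0.625, 0.875]` and extreme-high `(0.875, 1]`. A gene has
#' ASE if it falls in either extreme bin and non-ASE if it falls in the
#' middle bin; the moderate bins are treated as a separate, usually excluded,
#' class.
#'
#' @param prop_gt_half Numeric vector of values in `[0, 1]`.
#' @return A data frame prop_gt_half, bin (factor over the five bins),
#'   ase_class (`"ASE"`, `"moderate"`, `"non-ASE"`).
#' @examples
#' classify_ase(c(0.10, 0.50, 0.95))
#' @export
classify_ase <- function(prop_gt_half) {
  p <- prop_gt_half
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("prop_gt_half values must lie in [0, 1]")
  }
  bin <- character(length(p))
  bin[p < 0.125] <- "extreme-low"
  bin[p >= 0.125 & p < 0.375] <- "moderate-low"
  bin[p >= 0.375 & p <= 0.625] <- "non-ASE"
  bin[p > 0.625 & p <= 0.875] <- "moderate-high"
  bin[p > 0.875] <- "extreme-high"
  bin <- factor(bin, levels = ASE_BINS)
  cls <- ifelse(bin %in% c("extreme-low", "extreme-high"), "ASE",
                ifelse(bin == "non-ASE", "non-ASE", "moderate"))
  data.frame(prop_gt_half = p, bin = bin, ase_class = cls,
             stringsAsFactors = FALSE)
}
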