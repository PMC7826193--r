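#' Fit per-gene allele-specific expression by MCMC
#'
#' The central fitting function: for every gene/group combination passing
#' the pooled read filter, samples the focal-haplotype expression fraction
#' rho ([sample_rho()]), records the proportion of kept iterations with
#' rho > 0.5, and classifies it into the five ASE bins ([classify_ase()]).
#'
#' The default of 2,000 kept iterations (above the 500 minimum) controls the
#' Monte-Carlo error of the proportion statistic; the burn-in is 1,000
#' iterations.
#'
#' @param counts Allele count table: gene_id, group, replicate, focal_count,
#'   total_count (optionally chromosome).
#' @param min_reads Minimum pooled reads per gene/group (default 10).
#' @param n_burn,n_keep MCMC burn-in and kept iterations.
#' @param seed Integer seed for the whole fit.
#' @param proposal_sd Logit-scale random-walk proposal SD.
#' @param likelihood Passed to [sample_rho()]; the default
#'   orientation-invariant likelihood is the classification statistic.
#' @return An object of class `ase_fit` with a `results` data frame
#'   (gene_id, chromosome, group, focal_reads, total_reads, prop_gt_half,
#'   bin, ase_class, converged) and the fit settings. Methods: `print`,
#'   `summary`, `coef` (matrix of prop_gt_half, genes x groups), `plot`.
#' @examples
#' cfg <- sim_config(genes_per_chromosome = c(III = 8), seed = 3)
#' sim <- simulate_variants(cfg)
#' counts <- simulate_allele_counts(cfg, sim$truth)
#' fit <- ase_fit(counts, seed = 3)
#' fit
#' @export
ase_fit <- function(counts, min_reads = 10, n_burn = 1000, n_keep = 2000,
                    seed = 1, proposal_sd = 0.5,
                    likelihood = c("invariant", "identified")) {
  likelihood <- match.arg(likelihood)
  pooled <- min_read_filter(counts, threshold = min_reads)
  chrom_map <- NULL
  if (!is.null(counts$chromosome)) {
    chrom_map <- counts$chromosome[!duplicated(counts$gene_id)]
    names(chrom_map) <- counts$gene_id[!duplicated(counts$gene_id)]
  }
  kept <- pooled[pooled$retained, , drop = FALSE]
  with_seed(seed, {
    n <- nrow(kept)
    prop <- numeric(n)
    conv <- logical(n)
    for (i in seq_len(n)) {
      res <- rho_core(kept$focal_reads[i], kept$total_reads[i], n_burn,
                      n_keep, proposal_sd, likelihood == "invariant")
      prop[i] <- res$prop_gt_half
      conv[i] <- res$converged
    }
    cls <- classify_ase(prop)
    results <- data.frame(
      gene_id = kept$gene_id,
      chromosome = if (is.null(chrom_map)) NA_character_ else
        unname(chrom_map[kept$gene_id]),
      group = kept$group, focal_reads = kept$focal_reads,
      total_reads = kept$total_reads, prop_gt_half = prop,
      bin = cls$bin, ase_class = cls$ase_class, converged = conv,
      stringsAsFactors = FALSE)
    out <- list(results = results, n_filtered = sum(!pooled$retained),
                min_reads = min_reads, n_burn = n_burn, n_keep = n_keep,
                seed = seed, proposal_sd = proposal_sd,
                likelihood = likelihood, call = match.call())
    class(out) <- "ase_fit"
    out
  })
}

#' @export
print.ase_fit <- function(x, ...) {
  r <- x$results
  cat(sprintf("ASE fit: %d gene/group combinations (%d below %d pooled reads excluded)\n",
              nrow(r), x$n_filtered, x$min_reads))
  cat(sprintf("  %s likelihood; %d burn-in + %d kept iterations; seed %s\n",
              x$likelihood, x$n_burn, x$n_keep, format(x$seed)))
  print(table(group = r$group, class = r$ase_class))
  nc <- sum(!r$converged)
  if (nc > 0) cat(sprintf("  %d chain(s) flagged as possibly unconverged\n", nc))
  invisible(x)
}

#' @export
summary.ase_fit <- function(object, ...) {
  r <- object$results
  out <- list(bins = table(group = r$group, bin = r$bin),
              classes = table(group = r$group, class = r$ase_class),
              n = nrow(r), n_filtered = object$n_filtered,
              unconverged = sum(!r$converged))
  class(out) <- "summary.ase_fit"
  out
}

#' @export
print.summary.ase_fit <- function(x, ...) {
  cat(sprintf("%d gene/group fits (%d excluded by read filter, %d unconverged)\n",
              x$n, x$n_filtered, x$unconverged))
  cat("\nASE bins:\n"); print(x$bins)
  cat("\nASE classes:\n"); print(x$classes)
  invisible(x)
}

#' @export
coef.ase_fit <- function(object, ...) {
  r <- object$results
  genes <- unique(r$gene_id)
  groups <- unique(r$group)
  m <- matrix(NA_real_, length(genes), length(groups),
              dimnames = list(genes, groups))
  m[cbind(match(r$gene_id, genes), match(r$group, groups))] <- r$prop_gt_half
  m
}

#' @export
plot.ase_fit <- function(x, ...) {
  r <- x$results
  groups <- unique(r$group)
  op <- par(mfrow = c(1, length(groups)))
  on.exit(par(op))
  for (g in groups) {
    hist(r$prop_gt_half[r$group == g], breaks = seq(0, 1, by = 0.0625),
         main = g, xlab = "proportion of iterations with rho > 0.5", ...)
    abline(v = c(0.125, 0.375, 0.625, 0.875), lty = 2)
  }
  invisible(x)
}
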