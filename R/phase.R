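#' Phase gene haplotypes from long-read allele observations
#'
#' Greedy phasing over each gene's diagnostic sites: sites are processed in
#' genomic order; each read is oriented against the already-phased sites by
#' majority agreement, and the oriented reads then vote on the phase of the
#' next site. Returns two complementary haplotypes per gene. Haplotype 1 is
#' oriented canonically to carry the lexicographically smaller allele at the
#' gene's first diagnostic site, so the labeling is deterministic.
#'
#' @param long_reads Long-read observations, one row per read-site call:
#'   read_id, gene_id, position, allele.
#' @param diagnostic_sites Output of [find_diagnostic_sites()] (or the
#'   matching columns): gene_id, position, III_allele, IIIM_allele.
#' @return A named list (by gene) of `haplotype` objects: positions, `hap1`,
#'   `hap2` allele vectors and a `status` of `"phased"` or
#'   `"phasing-failed"` (no read covers any site).
#' @examples
#' ds <- data.frame(gene_id = "g", chromosome = "III", position = c(5, 9),
#'                  III_allele = c("A", "C"), IIIM_allele = c("G", "T"))
#' lr <- data.frame(read_id = rep(c("r1", "r2"), each = 2), gene_id = "g",
#'                  position = c(5, 9, 5, 9), allele = c("A", "C", "G", "T"))
#' phase_haplotypes(lr, ds)[["g"]]
#' @export
phase_haplotypes <- function(long_reads, diagnostic_sites) {
  genes <- unique(diagnostic_sites$gene_id)
  out <- vector("list", length(genes))
  names(out) <- genes
  for (g in genes) {
    ds <- diagnostic_sites[diagnostic_sites$gene_id == g, , drop = FALSE]
    ds <- ds[order(ds$position), , drop = FALSE]
    lr <- long_reads[long_reads$gene_id == g, , drop = FALSE]
    out[[g]] <- phase_one_gene(g, ds, lr)
  }
  out
}

phase_one_gene <- function(gene_id, ds, lr) {
  k <- nrow(ds)
  # allele 1 at each site: the lexicographically smaller of the pair
  a1 <- pmin(ds$III_allele, ds$IIIM_allele)
  a2 <- pmax(ds$III_allele, ds$IIIM_allele)

  hap_obj <- function(s, status) {
    hap1 <- ifelse(s > 0, a1, a2)
    hap2 <- ifelse(s > 0, a2, a1)
    structure(list(gene_id = gene_id, positions = ds$position,
                   hap1 = hap1, hap2 = hap2, status = status),
              class = "haplotype")
  }

  if (k == 1) {
    status <- if (nrow(lr) == 0) "phasing-failed" else "phased"
    return(hap_obj(1, status))
  }

  # encode read observations: +1 = allele 1, -1 = allele 2, 0 = other/absent
  reads <- split(lr, lr$read_id)
  enc <- matrix(0L, length(reads), k)
  for (i in seq_along(reads)) {
    rr <- reads[[i]]
    j <- match(rr$position, ds$position)
    ok <- !is.na(j)
    enc[i, j[ok]] <- ifelse(rr$allele[ok] == a1[j[ok]], 1L,
                            ifelse(rr$allele[ok] == a2[j[ok]], -1L, 0L))
  }
  if (length(reads) == 0 || all(enc == 0)) {
    return(hap_obj(rep(1, k), "phasing-failed"))
  }

  s <- integer(k)
  s[1] <- 1L
  # if no read covers site 1, anchor at the first covered site instead
  first <- which(colSums(enc != 0) > 0)[1]
  if (is.na(first)) first <- 1L
  phased <- rep(FALSE, k)
  s[first] <- 1L
  phased[first] <- TRUE
  for (j in setdiff(order(abs(seq_len(k) - first)), first)) {
    votes <- 0L
    for (i in seq_len(nrow(enc))) {
      if (enc[i, j] == 0L) next
      link <- sum(s[phased] * enc[i, phased])
      if (link == 0L) next
      votes <- votes + sign(link) * enc[i, j]
    }
    s[j] <- if (votes >= 0L) 1L else -1L
    phased[j] <- TRUE
  }
  # canonical orientation: hap1 carries allele 1 at the first site
  if (s[1] < 0) s <- -s
  hap_obj(s, "phased")
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("haplotypes for %s (%s) over %d site(s)\n", x$gene_id,
              x$status, length(x$positions)))
  cat("  hap1:", paste(x$hap1, collapse = " "), "\n")
  cat("  hap2:", paste(x$hap2, collapse = " "), "\n")
  invisible(x)
}

#' Assign the elevated allele of an ASE gene to the proto-Y or proto-X
#'
#' Matches the focal (first) phased haplotype to the proto-Y (III^M) allele
#' assignments at the gene's diagnostic sites by majority vote, then labels
#' the gene by which chromosomal allele is more highly expressed: the focal
#' haplotype when the ASE statistic exceeds 0.5, the other haplotype when it
#' is below. Ties in the vote, an exactly balanced statistic, or no
#' diagnostic overlap give `"undetermined"`.
#'
#' @param prop_gt_half The gene's ASE statistic (proportion of iterations
#'   with rho > 0.5), or an object with a `prop_gt_half` element.
#' @param haplotype A `haplotype` object from [phase_haplotypes()].
#' @param diagnostic_sites Diagnostic-site table with position, III_allele,
#'   IIIM_allele (for the gene).
#' @return `"IIIM-elevated"`, `"III-elevated"` or `"undetermined"`.
#' @export
assign_allele_direction <- function(prop_gt_half, haplotype,
                                    diagnostic_sites) {
  if (is.list(prop_gt_half)) prop_gt_half <- prop_gt_half$prop_gt_half
  ds <- diagnostic_sites
  if (!is.null(ds$gene_id)) {
    ds <- ds[ds$gene_id == haplotype$gene_id, , drop = FALSE]
  }
  j <- match(haplotype$positions, ds$position)
  ok <- !is.na(j)
  if (!any(ok) || haplotype$status != "phased") return("undetermined")
  m_iiim <- sum(haplotype$hap1[ok] == ds$IIIM_allele[j[ok]])
  m_iii <- sum(haplotype$hap1[ok] == ds$III_allele[j[ok]])
  if (m_iiim == m_iii) return("undetermined")
  focal_is <- if (m_iiim > m_iii) "IIIM" else "III"
  if (prop_gt_half == 0.5) return("undetermined")
  elevated <- if (prop_gt_half > 0.5) focal_is else
    setdiff(c("IIIM", "III"), focal_is)
  paste0(elevated, "-elevated")
}
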