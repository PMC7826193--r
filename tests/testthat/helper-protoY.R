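# small desk-scale configuration used across tests
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(genes_per_chromosome = c(I = 25, II = 25, III = 25,
                                            IV = 25, V = 25, X = 15),
                   seed = 11)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# independent oracle: brute force over every possible 35-bp window; a SNP is
# clustered iff some window [w, w+window-1] contains >= size SNPs including it
oracle_cluster_members <- function(chromosome, position, is_snp,
                                   size = 3, window = 35) {
  out <- logical(length(position))
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch & is_snp)
    p <- position[idx]
    if (length(p) == 0) next
    for (w in seq(min(p) - window + 1, max(p))) {
      inside <- which(p >= w & p <= w + window - 1)
      if (length(inside) >= size) out[idx[inside]] <- TRUE
    }
  }
  out
}

# independent oracle: two-sided Fisher p by full hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent oracle: distinct canonical k-mers by naive double loop
oracle_canonical_kmers <- function(seq, k) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nchar(seq)
  out <- character(0)
  if (n < k) return(out)
  for (i in 1:(n - k + 1)) {
    km <- substr(seq, i, i + k - 1)
    ch <- strsplit(km, "")[[1]]
    if (any(!ch %in% names(comp))) next
    rc <- paste(rev(unname(comp[ch])), collapse = "")
    out <- c(out, if (km <= rc) km else rc)
  }
  unique(out)
}

# agreement of an estimated haplotype pair with the true one, allowing for
# the arbitrary orientation
hap_agreement <- function(hap, true1, true2) {
  max(mean(hap$hap1 == true1), mean(hap$hap1 == true2))
}

# truth-table diagnostic sites in the layout find_diagnostic_sites() returns
truth_diag_sites <- function(truth) {
  ts <- truth$sites[truth$sites$is_diagnostic, , drop = FALSE]
  data.frame(chromosome = ts$chromosome, position = ts$position,
             gene_id = ts$gene_id, III_allele = ts$III_allele,
             IIIM_allele = ts$IIIM_allele, stringsAsFactors = FALSE)
}
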