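Package: protoY
Title: Divergence Between a Young Proto-Y Chromosome and Its Proto-X Homolog
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for detecting gene-by-gene divergence between a
    very young proto-Y chromosome and its homologous proto-X using RNA-seq
    variant calls and allele-specific expression (ASE). Implements per-gene
    relative heterozygosity contrasts between genotypic males and sex-reversed
    males, SNP-cluster mapping-bias filters, MCMC estimation of per-gene
    allele fractions with classification into ASE bins, diagnostic-site allele
    assignment and haplotype phasing from long reads, chromosome-level
    Wilcoxon and Fisher contrasts, a discordant sex-biased expression screen,
    and k-mer based detection of proto-Y contigs by the percent of k-mers
    unmatched by female reads. Includes a synthetic-data generator that
    emulates the two-genotype, three-replicate study design with ground truth
    for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR,
    Biostrings,
    rtracklayer,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
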