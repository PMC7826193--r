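revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Distinct canonical k-mers of one sequence: each window is collapsed with
# its reverse complement (lexicographic minimum); windows containing a
# non-ACGT character yield no k-mer.
canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0) return(character(0))
  unique(pmin(km, revcomp_chr(km)))
}

#' Build the female k-mer membership set
#'
#' Collects the distinct canonical k-mers (lexicographic minimum of each
#' k-mer and its reverse complement) of a set of female sequencing reads.
#' Windows containing an ambiguous base (N) contribute no k-mer.
#'
#' @param reads Character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param k k-mer length: odd, between 3 and 31 (default 15).
#' @return Character vector of canonical k-mers (the membership set).
#' @examples
#' build_kmer_set("ACGTACGTACGTACGTA", k = 15)
#' @export
build_kmer_set <- function(reads, k = 15) {
  if (!is.numeric(k) || k < 3 || k > 31 || k %% 2 != 1) {
    stop("k must be an odd integer between 3 and 31")
  }
  reads <- as.character(reads)
  if (length(reads) == 0) {
    warning("empty read set: the k-mer set is empty")
    return(character(0))
  }
  unique(unlist(lapply(reads, canonical_kmers, k = k), use.names = FALSE))
}

#' Percent of contig k-mers unmatched by female reads (%UFR)
#'
#' For each contig, computes the distinct canonical k-mers, counts how many
#' are absent from the female k-mer set, and reports
#' `100 * n_unmatched / n_distinct`. High values indicate sequence absent
#' from the female genome, i.e. candidate proto-Y contigs. Contigs shorter
#' than k (or with no valid k-mer) are excluded with a warning.
#'
#' @param contigs Named character vector of contig sequences (or a
#'   `DNAStringSet`).
#' @param female_set Canonical k-mer set from [build_kmer_set()].
#' @param k k-mer length (default 15); must match the female set.
#' @return A data frame contig_id, k, n_distinct, n_unmatched, pct_ufr.
#' @examples
#' fem <- build_kmer_set("ACGTTGCAAGCTTGCACGTAGCTAGCTA", k = 5)
#' percent_ufr(c(shared = "ACGTTGCAAGCTT", novel = "AAAAACCCCCAAAAA"),
#'             fem, k = 5)
#' @export
percent_ufr <- function(contigs, female_set, k = 15) {
  ids <- names(contigs)
  seqs <- as.character(contigs)
  if (is.null(ids)) ids <- sprintf("contig_%03d", seq_along(seqs))
  kms <- lapply(seqs, canonical_kmers, k = k)
  nd <- lengths(kms)
  bad <- nd == 0
  if (any(bad)) {
    warning(sum(bad), " contig(s) shorter than k (or with no valid k-mer) excluded: ",
            paste(ids[bad], collapse = ", "))
  }
  nu <- vapply(kms[!bad], function(x) sum(!x %in% female_set), 0L)
  data.frame(contig_id = ids[!bad], k = as.integer(k),
             n_distinct = nd[!bad], n_unmatched = as.integer(nu),
             pct_ufr = 100 * nu / nd[!bad],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify contigs as candidate proto-Y sequence
#'
#' Labels a contig `candidate-Y` when its percent of k-mers unmatched by
#' female reads is at least `threshold`, `not-Y` otherwise. The threshold is
#' configurable because no universal cutoff exists; 50 separates
#' predominantly male-specific from predominantly shared sequence.
#'
#' @param profiles Output of [percent_ufr()].
#' @param threshold %UFR cutoff in `[0, 100]` (default 50).
#' @return `profiles` with an added `label` column.
#' @export
classify_contigs <- function(profiles, threshold = 50) {
  profiles$label <- ifelse(profiles$pct_ufr >= threshold, "candidate-Y",
                           "not-Y")
  profiles
}
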