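#' Write variant sites as VCF v4.2
#'
#' Writes the two jointly genotyped groups as the two sample columns
#' `genotypic` and `sexreversed`, with FS, QD and the gene assignment in
#' INFO. Positions are 1-based as in the site table.
#'
#' @param sites Variant table as produced by [simulate_variants()].
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_variants_vcf <- function(sites, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene assignment\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "genotypic", "sexreversed", sep = "\t"))
  gt_index <- function(gt, ref, alts) {
    al <- strsplit(gt, "/", fixed = TRUE)[[1]]
    idx <- match(al, c(ref, alts)) - 1L
    paste(sort(idx), collapse = "/")
  }
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    alleles <- unique(c(strsplit(s$gt_G, "/", fixed = TRUE)[[1]],
                        strsplit(s$gt_SR, "/", fixed = TRUE)[[1]],
                        strsplit(s$alt, ",", fixed = TRUE)[[1]]))
    alts <- setdiff(alleles, s$ref)
    if (length(alts) == 0) alts <- strsplit(s$alt, ",", fixed = TRUE)[[1]]
    info <- sprintf("FS=%s;QD=%s%s", format(s$FS), format(s$QD),
                    if (is.na(s$gene_id)) "" else paste0(";GENE=", s$gene_id))
    paste(s$chromosome, s$position, ".", s$ref,
          paste(alts, collapse = ","), ".", "PASS", info, "GT",
          gt_index(s$gt_G, s$ref, alts), gt_index(s$gt_SR, s$ref, alts),
          sep = "\t")
  }, "")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF of jointly genotyped variants
#'
#' Parses a VCF v4.2 with two sample columns (genotypic group first,
#' sex-reversed group second), FS and QD in INFO, and an optional GENE INFO
#' key. Genotype indices are translated back to allele strings; sites are
#' returned sorted with 1-based positions. Records with a missing GT are an
#' error naming the offending record.
#'
#' @param path Path to the VCF.
#' @return A variant site table (chromosome, position, ref, alt,
#'   variant_class, gene_id, gt_G, gt_SR, FS, QD).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 3) {
    stop("VCF must carry GT calls for two sample columns")
  }
  gt_raw <- gt[, 2:3, drop = FALSE]
  pos <- as.integer(fix$POS)
  fs <- suppressWarnings(as.numeric(vcfR::extract.info(v, "FS")))
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  gene <- vcfR::extract.info(v, "GENE")

  decode <- function(code, ref, alt, record) {
    if (is.na(code) || code %in% c(".", "./.", ".|.")) {
      stop(sprintf("record %s is missing a GT call", record), call. = FALSE)
    }
    code <- sub(":.*$", "", code)
    idx <- as.integer(strsplit(code, "[/|]")[[1]]) + 1L
    alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])[idx]
    paste(sort(alleles), collapse = "/")
  }
  n <- nrow(fix)
  gt_g <- gt_sr <- character(n)
  for (i in seq_len(n)) {
    rec <- sprintf("%s:%s (line %d)", fix$CHROM[i], fix$POS[i], i)
    gt_g[i] <- decode(gt_raw[i, 1], fix$REF[i], fix$ALT[i], rec)
    gt_sr[i] <- decode(gt_raw[i, 2], fix$REF[i], fix$ALT[i], rec)
  }
  is_snp <- nchar(fix$REF) == 1 &
    vapply(strsplit(fix$ALT, ",", fixed = TRUE),
           function(a) all(nchar(a) == 1), TRUE)
  out <- data.frame(chromosome = fix$CHROM, position = pos, ref = fix$REF,
                    alt = fix$ALT,
                    variant_class = ifelse(is_snp, "SNP", "indel"),
                    gene_id = as.character(gene), gt_G = gt_g,
                    gt_SR = gt_sr, FS = fs, QD = qd,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chromosome, unique(out$chromosome)),
                   out$position), ]
  rownames(out) <- NULL
  out
}

#' Read a gene annotation table
#'
#' Accepts either a TSV with columns gene_id, chromosome, start, end
#' (1-based inclusive) or a BED file (0-based half-open; converted to
#' 1-based inclusive internally, with the BED name column as the gene id).
#'
#' @param path Path to the annotation.
#' @param format `"tsv"`, `"bed"`, or `"auto"` (by file extension).
#' @return A data frame gene_id, chromosome, start, end.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    return(data.frame(gene_id = gr$name,
                      chromosome = as.character(gr$seqnames),
                      start = gr$start, end = gr$end,
                      stringsAsFactors = FALSE))
  }
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read an allele count table
#'
#' TSV with columns gene_id, chromosome, group, replicate, focal_count,
#' total_count.
#'
#' @param path Path to the TSV.
#' @return The count table.
#' @export
read_allele_counts <- function(path) {
  x <- read_tsv(path)
  needed <- c("gene_id", "group", "replicate", "focal_count", "total_count")
  miss <- setdiff(needed, names(x))
  if (length(miss) > 0) {
    stop("allele count table is missing columns: ",
         paste(miss, collapse = ", "))
  }
  x
}

#' Write / read long-read allele observations
#'
#' On disk, one row per read: read_id, gene_id, comma-separated
#' site_positions, comma-separated alleles. In memory, one row per
#' read-site observation.
#'
#' @param long_reads Long-format observations (read_id, gene_id, position,
#'   allele).
#' @param path File path.
#' @return `write_long_reads` the path invisibly; `read_long_reads` the
#'   long-format table.
#' @export
write_long_reads <- function(long_reads, path) {
  sp <- split(long_reads, long_reads$read_id)
  out <- data.frame(
    read_id = names(sp),
    gene_id = vapply(sp, function(x) x$gene_id[1], ""),
    site_positions = vapply(sp, function(x)
      paste(x$position, collapse = ","), ""),
    alleles = vapply(sp, function(x) paste(x$allele, collapse = ","), ""),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$read_id), ]
  write_tsv(out, path)
}

#' @rdname write_long_reads
#' @export
read_long_reads <- function(path) {
  x <- read_tsv(path)
  pos <- strsplit(as.character(x$site_positions), ",", fixed = TRUE)
  al <- strsplit(x$alleles, ",", fixed = TRUE)
  n <- lengths(pos)
  out <- data.frame(read_id = rep(x$read_id, n),
                    gene_id = rep(x$gene_id, n),
                    position = as.integer(unlist(pos)),
                    allele = unlist(al), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
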