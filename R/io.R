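# File-format edges. FASTA goes through Biostrings; VCF reading goes through
# VariantAnnotation; the VCF writer emits the minimal biallelic GT:AD:DP
# dialect the rest of the package consumes. BED output is 0-based half-open.

#' Write genome sequences to FASTA
#'
#' @param x a `genome_truth` or a named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "genome_truth")) x$sequences else x
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names truncated at the first
#'   whitespace, as chromosome names).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write SSR loci to BED (0-based, half-open)
#'
#' Columns: chrom, start, end, name (motif class), score (repeat count),
#' strand (`+`; classes are strand-collapsed).
#'
#' @param loci data.frame from [scan_ssrs()] or a genome truth table.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  dt <- data.table::data.table(
    chrom = loci$chrom, start = loci$start, end = loci$end,
    name = loci$motif_class, score = loci$repeat_count, strand = "+")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a BED file of SSR loci
#'
#' @param path BED path (as written by [write_bed()]).
#' @return data.frame with `chrom`, `start`, `end`, `motif_class`,
#'   `repeat_count`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]),
             motif_class = if (ncol(dt) >= 4) as.character(dt[[4]]) else NA,
             repeat_count = if (ncol(dt) >= 5) as.integer(dt[[5]]) else NA,
             stringsAsFactors = FALSE)
}

#' Write a genotype matrix to VCF (GT:AD:DP)
#'
#' @param m a [genotype_matrix()].
#' @param path output path (plain-text `.vcf`).
#' @param chrom_lengths optional named vector, emitted as `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path, chrom_lengths = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=migseqr", con)
  if (!is.null(chrom_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  } else {
    writeLines(sprintf("##contig=<ID=%s>", unique(m$sites$chrom)), con)
  }
  writeLines(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic ',
           'depths for the ref and alt alleles">'),
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", m$samples), collapse = "\t"), con)
  if (n_sites(m) > 0) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[m$gt + 1L], nrow = n_sites(m))
    gt_str[is.na(gt_str)] <- "./."
    dp_str <- ifelse(is.na(m$dp), ".", as.character(m$dp))
    ad_str <- ifelse(is.na(m$ad_ref) | is.na(m$ad_alt), ".,.",
                     paste0(m$ad_ref, ",", m$ad_alt))
    cells <- matrix(paste(gt_str, ad_str, dp_str, sep = ":"),
                    nrow = n_sites(m))
    qual <- ifelse(is.na(m$sites$qual), ".",
                   format(m$sites$qual, trim = TRUE, scientific = FALSE))
    lines <- paste(m$sites$chrom, m$sites$pos, ".", m$sites$ref,
                   m$sites$alt, qual, "PASS", ".", "GT:AD:DP",
                   apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a multi-sample VCF (any ordering of GT/AD/DP in FORMAT, handled by
#' `VariantAnnotation`) into a [genotype_matrix()]. Only the first alternate
#' allele is represented; genotypes other than `0/0`, `0/1`, `1/0`, `1/1`
#' (phased or unphased) become missing.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(v))
  altl <- VariantAnnotation::alt(v)
  alt <- vapply(seq_along(altl), function(i) {
    a <- as.character(altl[[i]])
    paste(a, collapse = ",")
  }, character(1))
  qual <- VariantAnnotation::qual(v)
  g <- VariantAnnotation::geno(v)
  samples <- colnames(v)
  ns <- length(chrom)

  gt_raw <- g$GT
  gt_code <- matrix(NA_integer_, ns, length(samples))
  gt_norm <- gsub("|", "/", gt_raw, fixed = TRUE)
  gt_code[gt_norm %in% "0/0"] <- 0L
  gt_code[gt_norm %in% c("0/1", "1/0")] <- 1L
  gt_code[gt_norm %in% "1/1"] <- 2L

  dp <- if (!is.null(g$DP)) {
    d <- g$DP
    storage.mode(d) <- "integer"
    d
  } else NULL
  ad_ref <- ad_alt <- NULL
  if (!is.null(g$AD)) {
    ad <- g$AD
    pick <- function(k) {
      apply(ad, c(1, 2), function(x) {
        x <- x[[1]]
        if (length(x) >= k && !is.na(x[k])) as.integer(x[k]) else NA_integer_
      })
    }
    if (is.list(ad)) {
      ad_ref <- pick(1)
      ad_alt <- pick(2)
    } else if (length(dim(ad)) == 3) {
      ad_ref <- matrix(as.integer(ad[, , 1]), ns)
      ad_alt <- matrix(as.integer(ad[, , 2]), ns)
    }
  }
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               qual = as.numeric(qual), stringsAsFactors = FALSE),
    samples, gt_code, dp, ad_ref, ad_alt)
}

#' Write/read small TSV tables (phenotypes, labels, summaries)
#'
#' Thin deterministic wrappers over `data.table::fwrite`/`fread` with a fixed
#' dialect (tab separator, `\n` line endings, header row).
#'
#' @param x data.frame.
#' @param path TSV path.
#' @return `write_tsv`: `path` invisibly; `read_tsv`: a data.frame.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", eol = "\n", quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}
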