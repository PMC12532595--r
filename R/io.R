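# Readers/writers for the plain-text interchange formats the pipeline uses:
# dosage VCF (FORMAT/DS), COJO ".ma" summary statistics, BED/GFF3 gene
# models and TSV tables. All coordinates are 1-based inclusive internally;
# BED is written 0-based half-open, GFF3 1-based, per convention.

#' Write a genotype panel as a VCF with FORMAT/DS dosages
#'
#' @param panel A genotype panel.
#' @param path Output path (plain text, `.vcf`).
#' @param sample_ids Optional sample names; defaults to `ind00001..`.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(panel, path, sample_ids = NULL) {
  v <- panel$variants
  n <- nrow(panel$dosages)
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%05d", seq_len(n))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste0("##INFO=<ID=INFO,Number=1,Type=Float,",
                  "Description=\"Imputation quality\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], sprintf("%.0f", v$pos[j]), v$id[j], v$a2[j],
            v$a1[j], ".", "PASS",
            sprintf("INFO=%.2f", v$info[j]), "DS",
            format(panel$dosages[, j], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a dosage VCF (FORMAT/DS) into a genotype panel
#'
#' The ALT allele is taken as the effect allele (a1), matching
#' [write_dosage_vcf()].
#'
#' @param path VCF path.
#' @return A `"genotype_panel"` list.
#' @export
read_dosage_vcf <- function(path) {
  lines <- readLines(path)
  hline <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hline], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hline)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  m <- length(fields)
  dos <- matrix(NA_real_, length(samples), m)
  v <- data.frame(chrom = character(m), pos = numeric(m), id = character(m),
                  a1 = character(m), a2 = character(m), maf = NA_real_,
                  ploidy_class = "diploid", info = NA_real_,
                  stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- fields[[j]]
    v$chrom[j] <- f[1]; v$pos[j] <- as.numeric(f[2]); v$id[j] <- f[3]
    v$a2[j] <- f[4]; v$a1[j] <- f[5]
    v$info[j] <- as.numeric(sub("INFO=", "", f[8]))
    dos[, j] <- as.numeric(f[-(1:9)])
  }
  af <- colMeans(dos) / 2
  v$maf <- pmin(af, 1 - af)
  colnames(dos) <- v$id
  structure(list(variants = v, dosages = dos), class = "genotype_panel")
}

#' Write summary statistics in COJO ".ma" layout
#'
#' Columns: `SNP A1 A2 freq b se p N`, whitespace-delimited.
#'
#' @param sumstats Data frame with id, a1, a2, freq_a1, beta, se, p, n.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ma <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$id, A1 = sumstats$a1, A2 = sumstats$a2,
                    freq = sumstats$freq_a1, b = sumstats$beta,
                    se = sumstats$se, p = sumstats$p, N = sumstats$n)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a COJO ".ma" summary-statistic file
#'
#' @param path File path.
#' @param variants Optional variant table supplying chrom/pos keyed by id.
#' @return A summary-statistic data.frame (id, a1, a2, freq_a1, beta, se,
#'   z, p, n, plus chrom/pos when `variants` is given).
#' @export
read_ma <- function(path, variants = NULL) {
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  out <- data.frame(id = x$SNP, a1 = x$A1, a2 = x$A2, freq_a1 = x$freq,
                    beta = x$b, se = x$se, z = x$b / x$se, p = x$p, n = x$N,
                    stringsAsFactors = FALSE)
  if (!is.null(variants)) {
    i <- match(out$id, variants$id)
    out$chrom <- variants$chrom[i]
    out$pos <- variants$pos[i]
  }
  out
}

#' Write gene models as BED (0-based half-open) or GFF3 (1-based)
#'
#' @param genes Gene table (chrom, start, end, strand, symbol), 1-based
#'   inclusive coordinates.
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- data.frame(genes$chrom, sprintf("%.0f", genes$start - 1),
                      sprintf("%.0f", genes$end), genes$symbol, 0L,
                      genes$strand)
    utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE, sep = "\t")
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\tbagwas\tgene\t%.0f\t%.0f\t.\t%s\t.\tID=%s;Name=%s",
                       genes$chrom, genes$start, genes$end, genes$strand,
                       genes$symbol, genes$symbol))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' @param path File path; format inferred from extension.
#' @return Gene table with 1-based inclusive start/end.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    data.frame(chrom = as.character(x[[1]]), start = x[[2]] + 1L,
               end = x[[3]], strand = if (ncol(x) >= 6) x[[6]] else "+",
               symbol = x[[4]], stringsAsFactors = FALSE)
  } else {
    lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
    f <- strsplit(lines, "\t")
    data.frame(
      chrom = vapply(f, `[`, "", 1),
      start = as.numeric(vapply(f, `[`, "", 4)),
      end = as.numeric(vapply(f, `[`, "", 5)),
      strand = vapply(f, `[`, "", 7),
      symbol = sub(".*Name=([^;]+).*", "\\1", vapply(f, `[`, "", 9)),
      stringsAsFactors = FALSE)
  }
}
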