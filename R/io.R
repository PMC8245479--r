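#' Write a genotype dosage matrix as TSV
#'
#' Rows are individuals (first column `individual`), columns are marker
#' ids, cells 0/1/2 or NA.
#'
#' @param genotypes individuals x markers matrix.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(individual = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype dosage matrix from TSV
#'
#' @param path file written by [write_genotypes_tsv()] (first column
#'   individual ids, remaining columns marker dosages).
#' @return Numeric matrix with individual rownames.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write genotypes as a minimal VCF 4.2
#'
#' Biallelic markers on chromosome "1" at 1-based positions 1..n_markers,
#' GT-only FORMAT; dosage 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, missing -> ./.
#'
#' @param genotypes individuals x markers dosage matrix.
#' @param path output file (uncompressed text).
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  m <- ncol(genotypes)
  gt <- t(genotypes)                       # markers x individuals
  code <- matrix("./.", nrow = m, ncol = nrow(genotypes))
  code[!is.na(gt) & gt == 0] <- "0/0"
  code[!is.na(gt) & gt == 1] <- "0/1"
  code[!is.na(gt) & gt == 2] <- "1/1"
  body <- cbind(
    "1", seq_len(m),
    colnames(genotypes) %||% sprintf("M%04d", seq_len(m)),
    "A", "G", ".", "PASS", ".", "GT", code
  )
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a GT-only VCF into a dosage matrix
#'
#' Parses with \pkg{vcfR} and converts genotype calls to alternate-allele
#' dosages (0/1/2, NA for missing).
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return Individuals x markers numeric matrix.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  dos[gt %in% c("0/0")] <- 0
  dos[gt %in% c("0/1", "1/0")] <- 1
  dos[gt %in% c("1/1")] <- 2
  t(dos)
}

#' Write long-format phenotypes as CSV
#'
#' @param phenotypes data frame with columns individual, harvest, block,
#'   value.
#' @param path output file.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  stopifnot(all(c("individual", "harvest", "block", "value") %in%
                  names(phenotypes)))
  utils::write.csv(phenotypes[, c("individual", "harvest", "block", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format phenotypes from CSV
#'
#' @param path file with header individual,harvest,block,value.
#' @return Data frame.
#' @export
read_phenotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "harvest", "block", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("phenotype file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$individual <- as.character(df$individual)
  df
}
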