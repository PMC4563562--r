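# PLINK genotype readers and writers: text (.ped/.map) and binary
# (.bed/.bim/.fam, SNP-major v1) dialects, plus the phenotype/covariate TSV.

#' Write genotypes as PLINK text (.ped/.map)
#'
#' Dosage counts the A1 allele: 2 -> "A1 A1", 1 -> "A1 A2", 0 -> "A2 A2",
#' missing -> "0 0".
#'
#' @param G a [genotype_matrix()].
#' @param prefix path prefix.
#' @param status optional 0/1 phenotype (written as 2 = case, 1 = control in
#'   the .ped phenotype column; `-9` when absent).
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(G, prefix, status = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosage)
  phe <- if (is.null(status)) rep(-9L, n) else ifelse(status == 1, 2L, 1L)
  a1 <- G$snps$a1; a2 <- G$snps$a2
  m <- ncol(G$dosage)
  al <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    d <- G$dosage[, j]
    c1 <- ifelse(is.na(d), "0", ifelse(d >= 1, a1[j], a2[j]))
    c2 <- ifelse(is.na(d), "0", ifelse(d == 2, a1[j], a2[j]))
    al[, 2 * j - 1] <- c1
    al[, 2 * j] <- c2
  }
  ped <- cbind(G$sample_ids, G$sample_ids, "0", "0", "1", phe, al)
  write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(G$snps$chr, G$snps$id, 0, G$snps$pos),
              paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' @param prefix path prefix.
#' @return A list: `genotypes` (a [genotype_matrix()], dosage = A1 count
#'   where A1 is the first allele listed in the data per SNP), `status`
#'   (0/1 or `NA` from the .ped phenotype column).
#' @export
read_plink_text <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    stringsAsFactors = FALSE)
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  m <- nrow(map)
  n <- nrow(ped)
  if (ncol(ped) != 6 + 2 * m)
    .err(".ped column count does not match .map", "liabh2_format")
  dosage <- matrix(NA_integer_, n, m)
  a1v <- character(m); a2v <- character(m)
  for (j in seq_len(m)) {
    c1 <- ped[[6 + 2 * j - 1]]
    c2 <- ped[[6 + 2 * j]]
    als <- setdiff(unique(c(c1, c2)), "0")
    a1 <- if (length(als) >= 1) als[1] else "A"
    a2 <- if (length(als) >= 2) als[2] else
      if (a1 == "A") "B" else "A"
    ok <- c1 != "0" & c2 != "0"
    dosage[ok, j] <- (c1[ok] == a1) + (c2[ok] == a1)
    a1v[j] <- a1; a2v[j] <- a2
  }
  phe <- suppressWarnings(as.integer(ped[[6]]))
  status <- ifelse(phe == 2, 1L, ifelse(phe == 1, 0L, NA_integer_))
  snps <- data.frame(id = map[[2]], chr = map[[1]], pos = map[[4]],
                     a1 = a1v, a2 = a2v, stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dosage, snps, ped[[2]]), status = status)
}

#' Write genotypes as PLINK binary (.bed/.bim/.fam)
#'
#' SNP-major v1 layout (magic bytes `0x6c 0x1b 0x01`); two bits per call:
#' `00` = homozygous A1 (dosage 2), `10` = heterozygous, `11` = homozygous
#' A2 (dosage 0), `01` = missing.
#'
#' @inheritParams write_plink_text
#' @return `prefix`, invisibly.
#' @export
write_plink_bed <- function(G, prefix, status = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosage)
  m <- ncol(G$dosage)
  phe <- if (is.null(status)) rep(-9L, n) else ifelse(status == 1, 2L, 1L)
  write.table(data.frame(G$sample_ids, G$sample_ids, 0, 0, 1, phe),
              paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(G$snps$chr, G$snps$id, 0, G$snps$pos, G$snps$a1,
                         G$snps$a2),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit codes
  code <- matrix(1L, n, m)  # 01 = missing
  code[!is.na(G$dosage) & G$dosage == 2] <- 0L
  code[!is.na(G$dosage) & G$dosage == 1] <- 2L
  code[!is.na(G$dosage) & G$dosage == 0] <- 3L
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  i4 <- matrix(seq_len(4 * bytes_per_snp), nrow = 4)
  packed <- code[i4[1, ], , drop = FALSE] +
    code[i4[2, ], , drop = FALSE] * 4L +
    code[i4[3, ], , drop = FALSE] * 16L +
    code[i4[4, ], , drop = FALSE] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(packed)), con)
  close(con)
  invisible(prefix)
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' @param prefix path prefix.
#' @return A list: `genotypes` (a [genotype_matrix()]) and `status`
#'   (0/1/NA from the .fam phenotype column).
#' @export
read_plink_bed <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  f <- paste0(prefix, ".bed")
  expected <- 3 + bytes_per_snp * m
  if (file.info(f)$size != expected)
    .err(sprintf("%s has %d bytes; expected %d", f, file.info(f)$size,
                 expected), "liabh2_format")
  con <- file(f, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    .err("not a SNP-major PLINK v1 .bed file", "liabh2_format")
  raw <- readBin(con, "raw", bytes_per_snp * m)
  b <- as.integer(raw)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L,
                 (b %/% 64L) %% 4L)
  codes <- matrix(as.vector(codes), nrow = 4 * bytes_per_snp)
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_integer_, n, m)
  dosage[codes == 0L] <- 2L
  dosage[codes == 2L] <- 1L
  dosage[codes == 3L] <- 0L
  phe <- suppressWarnings(as.integer(fam[[6]]))
  status <- ifelse(phe == 2, 1L, ifelse(phe == 1, 0L, NA_integer_))
  snps <- data.frame(id = bim[[2]], chr = bim[[1]], pos = bim[[4]],
                     a1 = as.character(bim[[5]]), a2 = as.character(bim[[6]]),
                     stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dosage, snps, as.character(fam[[2]])),
       status = status)
}

#' Write a phenotype/covariate TSV
#'
#' Columns: `sample_id`, `status` (0/1), `subtype`, then any covariates.
#'
#' @param phenotypes data.frame as produced by
#'   [assign_liability_phenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate TSV
#' @param path input path (header required; needs `sample_id` and `status`).
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "status"), names(df))
  if (length(miss))
    .err(paste("phenotype file missing columns:",
               paste(miss, collapse = ", ")), "liabh2_schema")
  df
}
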