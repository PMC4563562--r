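#' Genotype matrix container
#'
#' Bundles an `n` samples x `m` SNPs dosage matrix (counts of the A1 allele:
#' 0/1/2, `NA` = missing) with SNP metadata and sample identifiers.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns.
#' @param snps data.frame with columns `id`, `chr`, `pos`, `a1`, `a2`
#'   (one row per SNP column of `dosage`).
#' @param sample_ids character vector of length `nrow(dosage)`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, sample_ids) {
  dosage <- as.matrix(dosage)
  if (!is.data.frame(snps) || nrow(snps) != ncol(dosage))
    .err("snps must be a data.frame with one row per SNP column",
         "liabh2_invalid_input")
  need <- c("id", "chr", "pos", "a1", "a2")
  miss <- setdiff(need, names(snps))
  if (length(miss))
    .err(paste("snps is missing columns:", paste(miss, collapse = ", ")),
         "liabh2_invalid_input")
  if (length(sample_ids) != nrow(dosage))
    .err("sample_ids length must equal nrow(dosage)", "liabh2_invalid_input")
  if (anyDuplicated(sample_ids))
    .err("duplicate sample ids", "liabh2_invalid_input")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- snps$id
  structure(list(dosage = dosage, snps = snps,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs, %d chromosome(s), %.3g%% missing\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$snps$chr)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (logical, integer or character).
#' @param j SNP index (logical, integer or character).
#' @param ... ignored.
#' @return A `genotype_matrix` restricted to the selected samples/SNPs.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$snps$id)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  x$snps[j, , drop = FALSE],
                  x$sample_ids[i])
}
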