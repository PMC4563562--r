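# Genetic relationship matrices from standardized SNP dosages, whole-set and
# per-chromosome, plus GCTA-compatible binary and gzipped-text serialization.

#' Genetic relationship matrix container
#'
#' @param values symmetric n x n matrix.
#' @param sample_ids character vector of length n.
#' @param n_snps_pairwise n x n matrix of per-pair non-missing SNP counts.
#' @param snp_subset character label describing the SNP subset (provenance).
#' @return An object of class `grm`.
#' @export
grm <- function(values, sample_ids, n_snps_pairwise = NULL,
                snp_subset = "all") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) .err("GRM must be square", "liabh2_invalid_input")
  if (length(sample_ids) != n)
    .err("sample_ids length must match GRM dimension", "liabh2_invalid_input")
  if (is.null(n_snps_pairwise)) n_snps_pairwise <- matrix(NA_real_, n, n)
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 n_snps_pairwise = n_snps_pairwise, snp_subset = snp_subset),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("grm: %d samples (subset: %s) | mean diag %.3f | off-diag mean %.2e sd %.2e\n",
              length(x$sample_ids), x$snp_subset, mean(diag(x$values)),
              mean(off), sd(off)))
  invisible(x)
}

#' Subset a GRM by sample
#' @param x a [grm()].
#' @param i sample index.
#' @param ... ignored.
#' @return The sub-GRM.
#' @export
`[.grm` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  grm(x$values[i, i, drop = FALSE], x$sample_ids[i],
      x$n_snps_pairwise[i, i, drop = FALSE], x$snp_subset)
}

#' Compute a genetic relationship matrix from genotype dosages
#'
#' Off-diagonal entries average `(x_ij - 2p_i)(x_ik - 2p_i) / (2p_i(1-p_i))`
#' over SNPs non-missing in both samples (allele frequencies `p_i` estimated
#' from the analysis sample); the default diagonal uses the GCTA form
#' `1 + mean[(x^2 - (1+2p)x + 2p^2) / (2p(1-p))]`, with
#' `diagonal = "crossprod"` selecting the plain standardized cross-product.
#' Monomorphic SNPs are dropped; missing genotypes are handled by per-pair
#' renormalization.
#'
#' @param G a [genotype_matrix()].
#' @param snp_subset optional SNP selection (indices, ids, or logical).
#' @param diagonal `"gcta"` (default) or `"crossprod"`.
#' @param subset_label provenance label stored in the result.
#' @return A [grm()].
#' @export
compute_grm <- function(G, snp_subset = NULL,
                        diagonal = c("gcta", "crossprod"),
                        subset_label = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  diagonal <- match.arg(diagonal)
  n <- nrow(G$dosage)
  if (n < 2) .err("need at least 2 samples", "liabh2_invalid_input")
  x <- G$dosage
  if (!is.null(snp_subset)) {
    if (is.character(snp_subset)) snp_subset <- match(snp_subset, G$snps$id)
    x <- x[, snp_subset, drop = FALSE]
  }
  storage.mode(x) <- "double"
  p <- colMeans(x, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly))
    .err("no polymorphic SNPs in subset", "liabh2_invalid_input")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  denom <- 2 * p * (1 - p)
  Z <- sweep(x, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(denom), "/")
  M <- !is.na(Z)
  Z[!M] <- 0
  cnt <- tcrossprod(M * 1)
  vals <- tcrossprod(Z) / pmax(cnt, 1)
  if (diagonal == "gcta") {
    # x^2 - (1+2p) x + 2 p^2, standardized
    D <- x^2 - sweep(x, 2, 1 + 2 * p, "*")
    D <- sweep(D, 2, 2 * p^2, "+")
    D <- sweep(D, 2, denom, "/")
    D[!M] <- 0
    diag(vals) <- 1 + rowSums(D) / pmax(diag(cnt), 1)
  }
  if (is.null(subset_label))
    subset_label <- if (is.null(snp_subset)) "all" else "subset"
  grm(vals, G$sample_ids, cnt, subset_label)
}

#' Per-chromosome genetic relationship matrices
#'
#' One GRM per chromosome carrying at least one polymorphic SNP; the union
#' of the subsets covers every SNP.
#'
#' @param G a [genotype_matrix()].
#' @param diagonal passed to [compute_grm()].
#' @return A named list of [grm()] objects (names = chromosome labels).
#' @export
per_chromosome_grms <- function(G, diagonal = "gcta") {
  stopifnot(inherits(G, "genotype_matrix"))
  chrs <- G$snps$chr
  if (is.null(chrs) || all(is.na(chrs)))
    .err("no chromosome labels present", "liabh2_invalid_input")
  out <- list()
  for (ch in unique(chrs)) {
    idx <- which(chrs == ch)
    g <- tryCatch(compute_grm(G, idx, diagonal,
                              subset_label = paste0("chr", ch)),
                  liabh2_invalid_input = function(e) NULL)
    if (!is.null(g)) out[[as.character(ch)]] <- g
  }
  if (!length(out)) .err("no polymorphic chromosome", "liabh2_invalid_input")
  out
}

#' Write a GRM in GCTA format
#'
#' Binary dialect (default): `.grm.bin` (lower triangle incl. diagonal,
#' row-major, 4-byte floats), `.grm.N.bin` (pair SNP counts, 4-byte floats),
#' `.grm.id` (FID IID, tab-separated). Text dialect: gzipped
#' `<prefix>.grm.gz` with lines `i j n_snps value` (1-based, lower triangle)
#' plus the same `.grm.id`.
#'
#' @param g a [grm()].
#' @param prefix path prefix.
#' @param format `"bin"` or `"gz"`.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(g, prefix, format = c("bin", "gz")) {
  stopifnot(inherits(g, "grm"))
  format <- match.arg(format)
  n <- length(g$sample_ids)
  # GCTA stores the lower triangle row-major: i = 1..n, j = 1..i
  idx_i <- rep(seq_len(n), seq_len(n))
  idx_j <- unlist(lapply(seq_len(n), seq_len))
  vals <- g$values[cbind(idx_i, idx_j)]
  cnts <- g$n_snps_pairwise[cbind(idx_i, idx_j)]
  cnts[is.na(cnts)] <- 0
  write.table(data.frame(g$sample_ids, g$sample_ids),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (format == "bin") {
    con <- file(paste0(prefix, ".grm.bin"), "wb")
    writeBin(as.numeric(vals), con, size = 4)
    close(con)
    con <- file(paste0(prefix, ".grm.N.bin"), "wb")
    writeBin(as.numeric(cnts), con, size = 4)
    close(con)
  } else {
    con <- gzfile(paste0(prefix, ".grm.gz"), "w")
    writeLines(sprintf("%d\t%d\t%.10g\t%.10g", idx_i, idx_j, cnts, vals), con)
    close(con)
  }
  invisible(prefix)
}

#' Read a GRM in GCTA format
#'
#' @param prefix path prefix (expects `.grm.id` plus `.grm.bin`/`.grm.N.bin`
#'   or `.grm.gz`).
#' @param format `"bin"` or `"gz"`; auto-detected from files present when
#'   `NULL`.
#' @return A [grm()].
#' @export
read_grm <- function(prefix, format = NULL) {
  idf <- paste0(prefix, ".grm.id")
  if (!file.exists(idf)) .err(paste("missing", idf), "liabh2_format")
  ids <- read.table(idf, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(ids)
  n_lt <- n * (n + 1) / 2
  idx_i <- rep(seq_len(n), seq_len(n))
  idx_j <- unlist(lapply(seq_len(n), seq_len))
  if (is.null(format))
    format <- if (file.exists(paste0(prefix, ".grm.bin"))) "bin" else "gz"
  if (format == "bin") {
    f <- paste0(prefix, ".grm.bin")
    if (file.info(f)$size != 4 * n_lt)
      .err(sprintf("%s has %d bytes; expected %d for %d samples",
                   f, file.info(f)$size, 4 * n_lt, n), "liabh2_format")
    con <- file(f, "rb")
    vals <- readBin(con, "numeric", n_lt, size = 4)
    close(con)
    nf <- paste0(prefix, ".grm.N.bin")
    cnts <- if (file.exists(nf)) {
      con <- file(nf, "rb")
      on.exit(close(con))
      readBin(con, "numeric", n_lt, size = 4)
    } else rep(NA_real_, n_lt)
  } else {
    tab <- read.table(gzfile(paste0(prefix, ".grm.gz")), header = FALSE)
    if (nrow(tab) != n_lt)
      .err("text GRM row count does not match id file", "liabh2_format")
    ord <- order(tab[[1]], tab[[2]])
    tab <- tab[ord, ]
    cnts <- tab[[3]]
    vals <- tab[[4]]
  }
  V <- matrix(0, n, n)
  V[cbind(idx_i, idx_j)] <- vals
  V[cbind(idx_j, idx_i)] <- vals
  Cn <- matrix(NA_real_, n, n)
  Cn[cbind(idx_i, idx_j)] <- cnts
  Cn[cbind(idx_j, idx_i)] <- cnts
  grm(V, ids[[2]], Cn, "file")
}
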