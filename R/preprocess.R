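#' Count normalization and unit-interval rescaling
#'
#' Raw RNA-seq counts are normalized for composition with trimmed-mean-of
#' M-values (TMM) scaling factors, transformed to log2 counts-per-million
#' with a small prior count, and finally rescaled gene-wise to the unit
#' interval so that propagation can treat expression as a proxy for the
#' presence of the active protein.
#'
#' @name preprocess
NULL

#' Read a gene count matrix from TSV
#'
#' First column = gene id, remaining columns = samples. Gzip accepted.
#'
#' @param path TSV file path.
#' @return Integer-ish numeric matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  .check_counts(m)
  m
}

.check_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("negative counts")
  invisible(counts)
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values between each sample and a reference sample,
#' assuming most genes are not differentially expressed. The reference is
#' the sample whose upper-quartile/library-size ratio is closest to the
#' mean of that ratio across samples. For each sample the factor is
#' 2^(weighted mean of per-gene log ratios M after two-sided trimming of
#' \code{trim_m} on M and \code{trim_a} on average abundance A), with
#' inverse approximate binomial variances as weights; genes with a zero
#' count in either member of the pair are excluded. Factors are rescaled
#' so their geometric mean is 1.
#'
#' @param counts Genes x samples non-negative matrix.
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  .check_counts(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  # reference: upper quartile of non-zero scaled counts closest to mean
  uq <- apply(counts, 2L, function(x) stats::quantile(x, 0.75)) / lib
  ref_i <- which.min(abs(uq - mean(uq)))
  ref <- counts[, ref_i]
  nR <- lib[ref_i]

  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]
    nO <- lib[j]
    keep <- obs > 0 & ref > 0
    if (!any(keep)) return(1)
    o <- obs[keep]; r <- ref[keep]
    M <- log2((o / nO) / (r / nR))
    A <- 0.5 * log2((o / nO) * (r / nR))
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)  # approx binomial var
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    n <- length(M)
    if (n == 0L) return(1)
    if (max(abs(M)) < 1e-6) return(1)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' entry = log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6),
#' the normalized log-count transform used upstream of activity
#' computation. Strictly monotone in the count.
#'
#' @param counts Genes x samples matrix.
#' @param factors Per-sample TMM factors (default [tmm_factors()]).
#' @param prior Pseudo-count (default 0.5).
#' @return List with \code{values} (log2 matrix) and \code{lib_factors}.
#' @export
log_cpm <- function(counts, factors = tmm_factors(counts), prior = 0.5) {
  .check_counts(counts)
  if (length(factors) != ncol(counts))
    stop("factors not aligned to samples")
  if (!is.null(names(factors)) &&
      !identical(names(factors), colnames(counts)))
    factors <- factors[colnames(counts)]
  eff <- colSums(counts) * factors
  if (any(!is.finite(eff)) || any(eff <= 0))
    stop("non-positive effective library size")
  vals <- log2(t((t(counts) + prior) / (eff + 2 * prior)) * 1e6)
  list(values = vals, lib_factors = factors)
}

#' Rescale a normalized matrix to the unit interval, gene-wise
#'
#' Per gene: values above the per-gene \code{trunc_quantile} quantile are
#' clipped, then min-max mapped to [0, 1]. Constant genes map to 0.5.
#'
#' @param norm Output of [log_cpm()] or a plain numeric matrix.
#' @param trunc_quantile Upper truncation quantile (default 0.99).
#' @return Genes x samples matrix with entries in [0, 1].
#' @export
rescale_unit <- function(norm, trunc_quantile = 0.99) {
  m <- if (is.list(norm)) norm$values else norm
  if (ncol(m) < 2L) stop("rescaling needs at least 2 samples")
  out <- t(apply(m, 1L, function(x) {
    q <- stats::quantile(x, trunc_quantile, names = FALSE)
    x <- pmin(x, q)
    rng <- range(x)
    if (rng[2] - rng[1] <= 0) return(rep(0.5, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }))
  dimnames(out) <- dimnames(m)
  out
}

#' Impute pathway genes missing from the expression matrix
#'
#' Pathway genes absent from the scaled matrix are appended as constant
#' rows equal to the grand mean of all scaled entries (or a fixed value).
#'
#' @param scaled Genes x samples matrix in [0, 1].
#' @param required_genes Gene ids the pathway catalog needs.
#' @param impute_value Override for the imputed constant (default: grand
#'   mean of \code{scaled}).
#' @return List with \code{values} (augmented matrix) and \code{imputed}
#'   (character vector of imputed gene ids).
#' @export
impute_missing <- function(scaled, required_genes, impute_value = NULL) {
  required_genes <- unique(as.character(required_genes))
  present <- intersect(required_genes, rownames(scaled))
  if (length(required_genes) && !length(present) && is.null(impute_value))
    stop("no measured pathway genes: cannot impute from the dataset")
  missing <- setdiff(required_genes, rownames(scaled))
  if (!length(missing))
    return(list(values = scaled, imputed = character()))
  val <- if (is.null(impute_value)) mean(scaled) else impute_value
  add <- matrix(val, nrow = length(missing), ncol = ncol(scaled),
                dimnames = list(missing, colnames(scaled)))
  list(values = rbind(scaled, add), imputed = missing)
}
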