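#' @include utils.R
NULL

#' Convert methylated/unmethylated intensities to beta values
#'
#' Element-wise `M / (M + U + offset)`. With a positive offset the result
#' is strictly below 1 for finite intensities; zero intensities give 0.
#'
#' @param M methylated intensity matrix, entries >= 0.
#' @param U unmethylated intensity matrix, same shape, entries >= 0.
#' @param offset nonnegative stabilising offset (default 100).
#' @return beta matrix in \[0, 1).
#' @examples
#' computeBeta(matrix(c(0, 100, 300)), matrix(c(0, 0, 100)))
#' @export
computeBeta <- function(M, U, offset = 100) {
  checkMatrix(M, "M"); checkMatrix(U, "U")
  if (!identical(dim(M), dim(U))) stopMsg("M and U must have the same shape")
  if (any(M < 0) || any(U < 0)) stopMsg("intensities must be nonnegative")
  if (offset < 0) stopMsg("offset must be nonnegative")
  beta <- M / (M + U + offset)
  dimnames(beta) <- dimnames(M)
  beta
}

#' Detection p-value probe filter
#'
#' A probe is kept iff the fraction of samples in which its detection
#' p-value exceeds `alpha` is at most `maxFailFrac`; "over 5% of
#' samples" removes, so the boundary (exactly 5%) is kept.
#'
#' @param p probes x samples detection p-value matrix in \[0, 1\].
#' @param alpha per-sample failure threshold (default 0.05).
#' @param maxFailFrac maximum tolerated failing-sample fraction
#'   (default 0.05).
#' @return named logical keep-mask over probes.
#' @examples
#' p <- matrix(0, 2, 100); p[1, 1:6] <- 0.9   # fails in 6% of samples
#' detectionFilter(p)
#' @export
detectionFilter <- function(p, alpha = 0.05, maxFailFrac = 0.05) {
  checkMatrix(p, "p")
  if (nrow(p) == 0L || ncol(p) == 0L) stopMsg("empty p-value matrix")
  if (any(p < 0) || any(p > 1)) stopMsg("p-values must lie in [0, 1]")
  failFrac <- rowMeans(p > alpha)
  keep <- failFrac <= maxFailFrac
  names(keep) <- rownames(p)
  keep
}

#' Remove blacklisted probes
#'
#' Drops probes on the sex chromosomes (X/Y) and probes flagged as
#' SNP-associated, preserving the order of survivors.
#'
#' @param beta probes x samples beta matrix with probe rownames.
#' @param ann annotation data.frame with columns `probe_id`, `chr`,
#'   `gene`, `snp_flag`; must cover every probe in `beta`.
#' @return the filtered beta matrix.
#' @export
dropBlacklisted <- function(beta, ann) {
  checkMatrix(beta, "beta")
  stopifnot(all(c("probe_id", "chr", "snp_flag") %in% colnames(ann)))
  if (anyDuplicated(ann$probe_id)) stopMsg("annotation probe_id must be unique")
  missing <- setdiff(rownames(beta), ann$probe_id)
  if (length(missing))
    stopMsg("probes missing from annotation: %s",
            paste(head(missing, 5L), collapse = ", "))
  a <- ann[match(rownames(beta), ann$probe_id), ]
  chr <- sub("^chr", "", as.character(a$chr))
  bad <- chr %in% c("X", "Y") | as.logical(a$snp_flag)
  if (all(bad)) stopMsg("all probes are blacklisted; downstream needs >= 1 probe")
  beta[!bad, , drop = FALSE]
}

#' Quantile normalization across samples
#'
#' Plain column quantile normalization: after normalization every column
#' shares the identical sorted value vector (the row-wise mean of the
#' per-column sorted inputs) and within-column ranks are preserved. Ties
#' are resolved by averaging the target values over tied ranks. A
#' single-column matrix is returned unchanged.
#'
#' @param x numeric matrix (features x samples), no missing values.
#' @return normalized matrix with the same dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(x) {
  checkMatrix(x, "x")
  if (ncol(x) < 2L) return(x)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Read a probe annotation TSV
#'
#' @param path TSV with columns probe_id, chr, gene, snp_flag.
#' @return data.frame with `snp_flag` coerced to logical.
#' @export
readAnnotation <- function(path) {
  ann <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  ann$snp_flag <- ann$snp_flag %in% c("TRUE", "true", "1", "T")
  ann
}
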