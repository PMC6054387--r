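#' Marker matrix construction and checks
#'
#' A marker matrix is an n x m numeric matrix of SNP dosages coded 0/1/2
#' (count of one allele), with line identifiers as row names and marker
#' identifiers as column names. Missing calls are `NA`.
#'
#' @param dosages n x m numeric matrix with entries in \{0, 1, 2, NA\}.
#' @param line_ids Optional character vector of n unique line identifiers
#'   (defaults to existing row names).
#' @param marker_ids Optional character vector of m marker identifiers.
#' @return The validated dosage matrix with dimnames set.
#' @export
marker_matrix <- function(dosages, line_ids = rownames(dosages),
                          marker_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(dosages)))
  if (anyDuplicated(line_ids)) stop("duplicate line identifiers")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(line_ids, marker_ids)
  dosages
}

## per-marker allele frequency of the counted allele, from non-missing calls
marker_freq <- function(geno) colMeans(geno, na.rm = TRUE) / 2

#' Filter markers on minor allele frequency and missingness
#'
#' Retains markers whose minor allele frequency (computed from non-missing
#' calls) is strictly greater than `maf_min` and whose missing fraction is
#' strictly below `max_missing`; i.e. markers with MAF <= `maf_min` or
#' missingness >= `max_missing` are excluded. Marker order is preserved.
#'
#' @param geno Dosage matrix from [marker_matrix()] (or any 0/1/2/NA matrix).
#' @param maf_min Minor-allele-frequency threshold in \[0, 0.5).
#' @param max_missing Missing-fraction threshold in \[0, 1\].
#' @return The filtered dosage matrix.
#' @export
filter_markers <- function(geno, maf_min = 0.05, max_missing = 0.20) {
  if (maf_min < 0 || maf_min >= 0.5) stop("`maf_min` must be in [0, 0.5)")
  if (max_missing < 0 || max_missing > 1) stop("`max_missing` must be in [0, 1]")
  geno <- as.matrix(geno)
  p <- marker_freq(geno)
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(geno))
  keep <- !is.na(maf) & maf > maf_min & miss < max_missing
  if (!any(keep))
    stop("all markers removed by the MAF/missingness filter", call. = FALSE)
  geno[, keep, drop = FALSE]
}

#' VanRaden method-1 genomic relationship matrix
#'
#' Computes K = Z Z' / (2 * sum_j p_j (1 - p_j)) where Z is the dosage matrix
#' column-centred at twice the sample allele frequency p_j. Missing dosages
#' are mean-imputed per marker (column mean of the non-missing calls) before
#' centring; allele frequencies are estimated from the sample itself.
#'
#' @param geno Dosage matrix (0/1/2/NA), lines in rows.
#' @return n x n symmetric relationship matrix with line ids as dimnames.
#' @examples
#' g <- rbind(L1 = c(M1 = 0), L2 = c(M1 = 2))
#' compute_grm(g)  # [[2, -2], [-2, 2]]
#' @export
compute_grm <- function(geno) {
  geno <- as.matrix(geno)
  if (ncol(geno) < 1) stop("need at least one marker")
  if (anyNA(geno)) {
    mu <- colMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(geno) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic; relationship matrix undefined",
         call. = FALSE)
  Z <- sweep(geno, 2, 2 * p)
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(rownames(geno), rownames(geno))
  K
}

## eigendecomposition of K + jitter, cached for the fast REML/Gibbs paths
kinship_eigen <- function(K, jitter = 1e-8) {
  if (inherits(K, "kinship_eigen")) return(K)
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8 * max(abs(K), 1))
    stop("kinship matrix is not symmetric")
  K <- (K + t(K)) / 2
  e <- eigen(K + diag(jitter, nrow(K)), symmetric = TRUE)
  structure(list(K = K, U = e$vectors, d = pmax(e$values, jitter),
                 ids = rownames(K)),
            class = "kinship_eigen")
}
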