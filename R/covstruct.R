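#' Residual covariance structures for multi-environment trials
#'
#' A `residual_structure` parameterizes the l x l between-environment residual
#' covariance matrix R0 of a MET model, where the full residual covariance is
#' R0 (x) I (Kronecker product, lines independent). Four kinds are supported:
#'
#' * `"IDV"`  -- homogeneous diagonal, one common variance: R0 = sigma2 * I.
#'   Parameters: `c(sigma2)`.
#' * `"IDH"`  -- heterogeneous diagonal: R0 = diag(sigma2_1, ..., sigma2_l).
#'   Parameters: `c(sigma2_1, ..., sigma2_l)`.
#' * `"US"`   -- unstructured symmetric positive-definite matrix.
#'   Parameters: lower triangle of R0 including the diagonal, column-major
#'   (`vech`), length l(l+1)/2.
#' * `"ANT1"` -- first-order antedependence: heterogeneous standard deviations
#'   sigma_1..sigma_l and adjacent (lag-1) correlations rho_1..rho_{l-1}; the
#'   correlation between environments i < j is the product
#'   rho_i * rho_{i+1} * ... * rho_{j-1}, so the inverse of R0 is tridiagonal.
#'   Parameters: `c(sigma_1, ..., sigma_l, rho_1, ..., rho_{l-1})`.
#'
#' @param kind One of `"US"`, `"IDH"`, `"IDV"`, `"ANT1"`.
#' @param l Number of environments (positive integer).
#' @param params Numeric parameter vector in the kind's canonical order above.
#' @return An object of class `residual_structure` with fields `kind`, `l`,
#'   `params`.
#' @examples
#' rs <- residual_structure("ANT1", 3, c(1, 2, 3, 0.5, 0.5))
#' build_covariance(rs)
#' @export
residual_structure <- function(kind, l, params) {
  kind <- match.arg(kind, c("US", "IDH", "IDV", "ANT1"))
  if (!is.numeric(l) || length(l) != 1L || l < 1 || l != round(l))
    stop("`l` must be a positive integer")
  l <- as.integer(l)
  params <- as.numeric(params)
  if (length(params) != param_count(kind, l))
    stop(sprintf("kind %s with l = %d requires %d parameters, got %d",
                 kind, l, param_count(kind, l), length(params)))
  rs <- structure(list(kind = kind, l = l, params = params),
                  class = "residual_structure")
  validate_structure(rs)
  rs
}

#' @export
print.residual_structure <- function(x, ...) {
  cat(sprintf("<residual_structure %s, l = %d>\n", x$kind, x$l))
  print(build_covariance(x))
  invisible(x)
}

## internal sanity checks; PD of US/ANT1 is ultimately enforced by the
## unconstrained parameterization, this validates direct construction
validate_structure <- function(rs) {
  l <- rs$l
  p <- rs$params
  switch(rs$kind,
    IDV = if (p[1] < 0) stop("IDV variance must be >= 0"),
    IDH = if (any(p < 0)) stop("IDH variances must be >= 0"),
    ANT1 = {
      if (any(p[seq_len(l)] < 0)) stop("ANT1 standard deviations must be >= 0")
      if (l > 1 && any(abs(p[(l + 1):(2 * l - 1)]) >= 1))
        stop("ANT1 adjacent correlations must lie in (-1, 1)")
    },
    US = {
      S <- vech_to_sym(p, l)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= -1e-10 * max(abs(ev), 1))
        stop("US parameter vector does not give a positive-definite matrix",
             call. = FALSE)
    })
  invisible(rs)
}

## vech (lower triangle incl. diagonal, column-major) helpers
vech_to_sym <- function(v, l) {
  S <- matrix(0, l, l)
  S[lower.tri(S, diag = TRUE)] <- v
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

sym_to_vech <- function(S) S[lower.tri(S, diag = TRUE)]

#' Number of free parameters of a covariance structure
#'
#' `ANT1` needs l standard deviations plus l - 1 adjacent correlations,
#' i.e. l + (l - 1) = 2l - 1 parameters; `IDV` one; `IDH` l. For `US` the
#' default is the full count l(l+1)/2 (variances plus covariances); set
#' `us_full = FALSE` to count covariances only, l(l-1)/2, a convention that
#' appears in parts of the MET literature.
#'
#' @param kind Structure kind (`"US"`, `"IDH"`, `"IDV"`, `"ANT1"`).
#' @param l Number of environments.
#' @param us_full For `"US"`: count variances and covariances (`TRUE`,
#'   default) or covariances only (`FALSE`).
#' @return Integer parameter count.
#' @export
param_count <- function(kind, l, us_full = TRUE) {
  kind <- match.arg(kind, c("US", "IDH", "IDV", "ANT1"))
  if (l < 1 || l != round(l)) stop("`l` must be a positive integer")
  l <- as.integer(l)
  switch(kind,
    IDV = 1L,
    IDH = l,
    ANT1 = 2L * l - 1L,
    US = if (us_full) (l * (l + 1L)) %/% 2L else (l * (l - 1L)) %/% 2L)
}

#' Build the l x l covariance matrix of a residual structure
#'
#' @param rs A [residual_structure()].
#' @return The l x l symmetric covariance matrix R0.
#' @export
build_covariance <- function(rs) {
  stopifnot(inherits(rs, "residual_structure"))
  l <- rs$l
  p <- rs$params
  switch(rs$kind,
    IDV = diag(p[1], l),
    IDH = diag(p, l),
    US  = vech_to_sym(p, l),
    ANT1 = {
      sig <- p[seq_len(l)]
      rho <- if (l > 1) p[(l + 1):(2 * l - 1)] else numeric(0)
      S <- diag(sig^2, l)
      if (l > 1) {
        for (i in 1:(l - 1)) for (j in (i + 1):l) {
          S[i, j] <- S[j, i] <- sig[i] * sig[j] * prod(rho[i:(j - 1)])
        }
      }
      S
    })
}

#' Inverse of a residual covariance structure
#'
#' Exact inverse of [build_covariance()]. For `ANT1` the inverse is
#' tridiagonal: every entry with |i - j| >= 2 vanishes.
#'
#' @param rs A [residual_structure()].
#' @return The l x l inverse covariance matrix.
#' @export
inverse_covariance <- function(rs) {
  S <- build_covariance(rs)
  ch <- tryCatch(chol(S), error = function(e)
    stop(sprintf("%s covariance matrix is singular or not positive definite",
                 rs$kind), call. = FALSE))
  chol2inv(ch)
}

#' Map a residual structure to and from unconstrained coordinates
#'
#' A smooth bijection used by the REML optimizer and the Metropolis updates:
#' variances/standard deviations are log-transformed, ANT1 correlations use
#' Fisher's z (atanh), and US matrices use a log-diagonal Cholesky
#' parameterization. Positive definiteness is guaranteed for every finite
#' unconstrained vector, so optimizers never leave the feasible set.
#'
#' @param rs A [residual_structure()].
#' @return `unconstrained_transform`: a real vector of length
#'   `param_count(kind, l)`.
#' @seealso [inverse_transform()]
#' @export
unconstrained_transform <- function(rs) {
  stopifnot(inherits(rs, "residual_structure"))
  l <- rs$l
  p <- rs$params
  switch(rs$kind,
    IDV = log(p),
    IDH = log(p),
    ANT1 = c(log(p[seq_len(l)]),
             if (l > 1) atanh(p[(l + 1):(2 * l - 1)])),
    US = chol_log_theta(vech_to_sym(p, l)))
}

#' @rdname unconstrained_transform
#' @param theta Finite real vector in unconstrained coordinates.
#' @param kind,l Structure kind and dimension, as in [residual_structure()].
#' @return `inverse_transform`: the [residual_structure()] mapping to `theta`.
#' @export
inverse_transform <- function(theta, kind, l) {
  kind <- match.arg(kind, c("US", "IDH", "IDV", "ANT1"))
  if (any(!is.finite(theta))) stop("non-finite unconstrained parameter vector")
  params <- switch(kind,
    IDV = exp(theta),
    IDH = exp(theta),
    ## clamp the Fisher-z coordinates so tanh stays strictly inside (-1, 1)
    ## in double precision even when an optimizer wanders far out
    ANT1 = c(exp(theta[seq_len(l)]),
             if (l > 1) tanh(pmin(pmax(theta[(l + 1):(2 * l - 1)], -18),
                                  18))),
    US = sym_to_vech(chol_log_matrix(theta, l)))
  residual_structure(kind, l, params)
}

## log-diagonal Cholesky coordinates of an SPD matrix: theta holds the lower
## triangle of L (S = L L') column-major with log-ed diagonal entries
chol_log_theta <- function(S) {
  L <- t(chol(S))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

chol_log_matrix <- function(theta, l) {
  L <- matrix(0, l, l)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

## Serialization of a structure to/from a flat config block
structure_to_config <- function(rs) {
  l <- rs$l
  p <- rs$params
  switch(rs$kind,
    IDV = list(kind = "IDV", l = l, sigma2 = p[1]),
    IDH = list(kind = "IDH", l = l, sigma2 = p),
    US  = list(kind = "US", l = l, vech = p),
    ANT1 = list(kind = "ANT1", l = l, sigma = p[seq_len(l)],
                rho = if (l > 1) p[(l + 1):(2 * l - 1)] else numeric(0)))
}

structure_from_config <- function(cfg, l = NULL) {
  kind <- match.arg(cfg$kind, c("US", "IDH", "IDV", "ANT1"))
  params <- switch(kind,
    IDV = cfg$sigma2,
    IDH = cfg$sigma2,
    US  = cfg$vech,
    ANT1 = c(cfg$sigma, cfg$rho))
  if (is.null(l)) {
    l <- switch(kind,
      IDV = if (is.null(cfg$l)) stop("IDV config needs `l`") else cfg$l,
      IDH = length(cfg$sigma2),
      US  = (sqrt(8 * length(cfg$vech) + 1) - 1) / 2,
      ANT1 = length(cfg$sigma))
  }
  residual_structure(kind, l, params)
}
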