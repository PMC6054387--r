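#' Variance components of the three MET models
#'
#' Containers pairing each model with its variance parameters:
#' * Model 1 (multivariate GBLUP): `G0`, the l x l unstructured genetic
#'   covariance between environments, and `R0`, a [residual_structure()];
#'   full covariances are G0 (x) K for breeding values and R0 (x) I for
#'   residuals.
#' * Model 2 (compound-symmetry G-by-E model): main genetic variance
#'   `sigma_g2` (u ~ N(0, sigma_g2 K)), interaction variance `sigma_v2`
#'   (v ~ N(0, sigma_v2 I (x) K)) and residual variance `sigma_e2`, a scalar
#'   (IDV) or one value per environment (IDH).
#' * Model 3 (univariate GBLUP): `sigma_g2` and `sigma_e2` for one
#'   environment.
#'
#' @param G0 l x l symmetric positive-definite genetic covariance.
#' @param R0 A [residual_structure()].
#' @param sigma_g2,sigma_v2,sigma_e2 Positive variances (see above).
#' @return An object of class `variance_components` with a `model` tag.
#' @name variance_components
NULL

#' @rdname variance_components
#' @export
vc_model1 <- function(G0, R0) {
  G0 <- as.matrix(G0)
  stopifnot(inherits(R0, "residual_structure"), all(dim(G0) == R0$l))
  if (max(abs(G0 - t(G0))) > 1e-8 * max(abs(G0), 1))
    stop("G0 must be symmetric")
  structure(list(model = 1L, G0 = (G0 + t(G0)) / 2, R0 = R0, l = R0$l),
            class = "variance_components")
}

#' @rdname variance_components
#' @export
vc_model2 <- function(sigma_g2, sigma_v2, sigma_e2) {
  stopifnot(sigma_g2 > 0, sigma_v2 > 0, all(sigma_e2 > 0))
  structure(list(model = 2L, sigma_g2 = sigma_g2, sigma_v2 = sigma_v2,
                 sigma_e2 = sigma_e2),
            class = "variance_components")
}

#' @rdname variance_components
#' @export
vc_model3 <- function(sigma_g2, sigma_e2) {
  stopifnot(sigma_g2 > 0, sigma_e2 > 0)
  structure(list(model = 3L, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
            class = "variance_components")
}

#' Build the design of a MET mixed model
#'
#' Validates the long phenotype table, orders the observed records
#' environment-major (all lines of environment 1, then environment 2, ...)
#' and constructs the fixed-effect incidence matrix of the requested model:
#' one intercept per environment for Model 1; a grand mean plus
#' sum-to-zero environment effects for Model 2; a single intercept for
#' Model 3 (which expects records from exactly one environment). Rows for
#' unobserved cells are omitted, but the random effects keep all `line_ids`,
#' so breeding values are predicted for unphenotyped lines too.
#'
#' @param phenotypes Data frame with columns `line`, `env`, `value`
#'   (`NA` = missing cell) and optionally `observed`.
#' @param line_ids Character vector of all line identifiers (must contain
#'   every phenotyped line).
#' @param model 1, 2 or 3.
#' @param env_levels Optional environment ordering (default: order of first
#'   appearance).
#' @return An object of class `met_design`.
#' @export
build_design <- function(phenotypes, line_ids, model = 1,
                         env_levels = NULL, allow_empty = FALSE) {
  stopifnot(all(c("line", "env", "value") %in% names(phenotypes)))
  model <- as.integer(model)
  stopifnot(model %in% 1:3)
  ph <- phenotypes
  ph$line <- as.character(ph$line)
  ph$env <- as.character(ph$env)
  unknown <- setdiff(ph$line, line_ids)
  if (length(unknown))
    stop("phenotyped lines absent from `line_ids`: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (anyDuplicated(ph[c("line", "env")]))
    stop("duplicate (line, env) phenotype records")
  if (is.null(env_levels)) env_levels <- unique(ph$env)
  if (!all(ph$env %in% env_levels)) stop("unknown environment label")
  l <- length(env_levels)
  if (model == 3L && l != 1L)
    stop("Model 3 is univariate: supply records from a single environment")

  obs_flag <- !is.na(ph$value)
  if (!is.null(ph$observed)) obs_flag <- obs_flag & ph$observed
  ph <- ph[obs_flag, , drop = FALSE]
  if (nrow(ph) == 0 && !allow_empty) stop("no observed phenotype records")
  line_idx <- match(ph$line, line_ids)
  env_idx <- match(ph$env, env_levels)
  ord <- order(env_idx, line_idx)
  ph <- ph[ord, , drop = FALSE]
  line_idx <- line_idx[ord]
  env_idx <- env_idx[ord]
  n <- length(line_ids)
  N <- nrow(ph)

  X <- switch(model,
    `1` = { # block-diagonal environment intercepts
      M <- matrix(0, N, l, dimnames = list(NULL, env_levels))
      M[cbind(seq_len(N), env_idx)] <- 1
      M
    },
    `2` = { # grand mean + l environment effects, sum-to-zero constrained
      M <- if (l == 1) matrix(1, N, 1, dimnames = list(NULL, "mu"))
      else {
        C <- stats::contr.sum(l)
        M2 <- cbind(1, C[env_idx, , drop = FALSE])
        colnames(M2) <- c("mu", paste0("env", seq_len(l - 1)))
        M2
      }
      attr(M, "n_cols_unconstrained") <- 1L + l  # grand mean + one per env
      M
    },
    `3` = matrix(1, N, 1, dimnames = list(NULL, "mu")))

  obs_mask <- matrix(FALSE, n, l, dimnames = list(line_ids, env_levels))
  obs_mask[cbind(line_idx, env_idx)] <- TRUE
  structure(list(y = as.numeric(ph$value), X = X,
                 line_idx = line_idx, env_idx = env_idx,
                 n = n, l = l, N = N, model = model,
                 line_ids = line_ids, env_levels = env_levels,
                 obs_mask = obs_mask),
            class = "met_design")
}

#' @export
print.met_design <- function(x, ...) {
  cat(sprintf("<met_design model %d: %d records, %d lines, %d environments>\n",
              x$model, x$N, x$n, length(x$env_levels)))
  invisible(x)
}

## TRUE iff every (line, env) cell is observed
design_is_complete <- function(design) all(design$obs_mask)

## marginal covariance V of the observed records (dense)
build_V <- function(design, vc, K) {
  K <- as_kinship(K, design$line_ids)
  i <- design$line_idx
  e <- design$env_idx
  KII <- K[i, i, drop = FALSE]
  same <- outer(i, i, `==`)
  if (vc$model == 1L) {
    G0 <- vc$G0
    R0 <- build_covariance(vc$R0)
    G0[e, e, drop = FALSE] * KII + R0[e, e, drop = FALSE] * same
  } else if (vc$model == 2L) {
    se <- rep(vc$sigma_e2, length.out = design$l)
    vc$sigma_g2 * KII + vc$sigma_v2 * KII * outer(e, e, `==`) +
      diag(se[e], design$N)
  } else {
    vc$sigma_g2 * KII + diag(vc$sigma_e2, design$N)
  }
}

as_kinship <- function(K, line_ids) {
  if (inherits(K, "kinship_eigen")) K <- K$K
  K <- as.matrix(K)
  if (!is.null(rownames(K)) && !identical(rownames(K), line_ids)) {
    if (!all(line_ids %in% rownames(K)))
      stop("kinship matrix is missing some lines")
    K <- K[line_ids, line_ids]
  }
  if (nrow(K) != length(line_ids))
    stop("kinship dimension does not match the number of lines")
  K
}

## GLS / conditional-mean solution path, shared by solve_mme and run_cv
gls_solve <- function(design, vc, K) {
  K <- as_kinship(K, design$line_ids)
  V <- build_V(design, vc, K)
  ch <- tryCatch(chol(V), error = function(e)
    stop("marginal covariance V is singular: ", conditionMessage(e),
         call. = FALSE))
  X <- design$X
  y <- design$y
  ViX <- backsolve(ch, forwardsolve(t(ch), X))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(X, Viy))
  r <- y - X %*% beta
  w <- backsolve(ch, forwardsolve(t(ch), r))
  list(beta = drop(beta), w = drop(w), chV = ch, XtViX = XtViX,
       resid = drop(r), Viy = Viy, ViX = ViX)
}

## random-effect predictions from GLS weights w = V^{-1}(y - X beta)
gls_blup <- function(design, vc, K, w) {
  K <- as_kinship(K, design$line_ids)
  i <- design$line_idx
  e <- design$env_idx
  n <- design$n
  l <- design$l
  Ksel <- K[, i, drop = FALSE]
  if (vc$model == 1L) {
    u <- sapply(seq_len(l), function(f) drop(Ksel %*% (w * vc$G0[f, e])))
    u <- matrix(u, n, l, dimnames = list(design$line_ids, design$env_levels))
    list(u = u, v = NULL, gebv = u)
  } else if (vc$model == 2L) {
    u <- drop(vc$sigma_g2 * (Ksel %*% w))
    v <- matrix(0, n, l, dimnames = list(design$line_ids, design$env_levels))
    for (f in seq_len(l)) {
      rows <- which(e == f)
      v[, f] <- vc$sigma_v2 * drop(K[, i[rows], drop = FALSE] %*% w[rows])
    }
    gebv <- v + u
    names(u) <- design$line_ids
    list(u = u, v = v, gebv = gebv)
  } else {
    u <- drop(vc$sigma_g2 * (Ksel %*% w))
    names(u) <- design$line_ids
    gebv <- matrix(u, n, 1, dimnames = list(design$line_ids,
                                            design$env_levels))
    list(u = u, v = NULL, gebv = gebv)
  }
}

#' Solve the mixed model equations at fixed variance components
#'
#' Jointly computes BLUEs of the fixed effects and BLUPs of the breeding
#' values (and, for Model 2, the G-by-E interaction effects), either through
#' Henderson's mixed model equations (`method = "mme"`) or through the
#' equivalent GLS / multivariate-normal conditional-mean formulation
#' (`method = "gls"`, the default route for `"auto"`). The two routes give
#' identical answers up to numerical error. Genomic estimated breeding
#' values are `u` per environment for Model 1, `u + v_e` for Model 2 and `u`
#' for Model 3.
#'
#' @param design A [build_design()] object.
#' @param vc Matching [variance_components].
#' @param K Kinship matrix over `design$line_ids` (or `kinship_eigen`).
#' @param method `"auto"`, `"gls"` or `"mme"`.
#' @return An object of class `met_fit` with `beta_hat`, `u_hat`, `v_hat`,
#'   `gebv`, `loglik` (restricted log-likelihood at `vc`) and metadata.
#' @export
solve_mme <- function(design, vc, K, method = c("auto", "gls", "mme")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "met_design"),
            inherits(vc, "variance_components"))
  if (vc$model != design$model)
    stop("variance components are for model ", vc$model,
         " but the design is for model ", design$model)
  if (method == "mme") return(solve_mme_henderson(design, vc, K))
  g <- gls_solve(design, vc, K)
  b <- gls_blup(design, vc, K, g$w)
  ll <- reml_ll_from_gls(design, g)
  new_met_fit(design, vc, beta = g$beta, u = b$u, v = b$v, gebv = b$gebv,
              loglik = ll, method = "gls")
}

new_met_fit <- function(design, vc, beta, u, v, gebv, loglik, method) {
  beta <- drop(beta)
  names(beta) <- colnames(design$X)
  env_means <- if (design$model == 2L && design$l > 1) {
    C <- stats::contr.sum(design$l)
    mu <- beta[1] + drop(C %*% beta[-1])
    stats::setNames(mu, design$env_levels)
  } else stats::setNames(drop(design$X[!duplicated(design$env_idx), ,
                                       drop = FALSE] %*% beta),
                         design$env_levels[unique(design$env_idx)])
  structure(list(beta_hat = beta, env_means = env_means, u_hat = u,
                 v_hat = v, gebv = gebv, loglik = loglik, vc = vc,
                 model = design$model, line_ids = design$line_ids,
                 env_levels = design$env_levels, method = method),
            class = "met_fit")
}

#' @export
print.met_fit <- function(x, ...) {
  cat(sprintf("<met_fit model %d (%s): %d lines, loglik %.4f>\n",
              x$model, x$method, length(x$line_ids), x$loglik))
  invisible(x)
}

## Henderson MME route: dense, used as the canonical small-scale solver and
## cross-checked against the GLS route in the tests
solve_mme_henderson <- function(design, vc, K) {
  K <- as_kinship(K, design$line_ids)
  n <- design$n
  l <- design$l
  N <- design$N
  i <- design$line_idx
  e <- design$env_idx
  X <- design$X
  y <- design$y
  Kinv <- chol2inv(chol(K + diag(1e-8, n)))

  if (vc$model == 1L) {
    R0 <- build_covariance(vc$R0)
    Rinv <- matrix(0, N, N)
    for (ln in unique(i)) {
      rows <- which(i == ln)
      Rinv[rows, rows] <- solve(R0[e[rows], e[rows], drop = FALSE])
    }
    Z <- matrix(0, N, n * l)
    Z[cbind(seq_len(N), (e - 1L) * n + i)] <- 1
    Ginv <- kronecker(solve(vc$G0), Kinv)
    C <- rbind(cbind(crossprod(X, Rinv %*% X), crossprod(X, Rinv %*% Z)),
               cbind(crossprod(Z, Rinv %*% X),
                     crossprod(Z, Rinv %*% Z) + Ginv))
    rhs <- c(crossprod(X, Rinv %*% y), crossprod(Z, Rinv %*% y))
    sol <- solve(C, rhs)
    p <- ncol(X)
    beta <- sol[seq_len(p)]
    u <- matrix(sol[-seq_len(p)], n, l,
                dimnames = list(design$line_ids, design$env_levels))
    fit <- new_met_fit(design, vc, beta, u, v = NULL, gebv = u,
                       loglik = restricted_loglik(design, vc, K),
                       method = "mme")
  } else if (vc$model == 2L) {
    se <- rep(vc$sigma_e2, length.out = l)
    rinv <- 1 / se[e]
    Zu <- matrix(0, N, n)
    Zu[cbind(seq_len(N), i)] <- 1
    W <- matrix(0, N, n * l)
    W[cbind(seq_len(N), (e - 1L) * n + i)] <- 1
    ZZ <- cbind(Zu, W)
    Ginv <- rbind(
      cbind(Kinv / vc$sigma_g2, matrix(0, n, n * l)),
      cbind(matrix(0, n * l, n), kronecker(diag(l), Kinv / vc$sigma_v2)))
    XtR <- t(X * rinv)
    ZtR <- t(ZZ * rinv)
    C <- rbind(cbind(XtR %*% X, XtR %*% ZZ),
               cbind(ZtR %*% X, ZtR %*% ZZ + Ginv))
    rhs <- c(XtR %*% y, ZtR %*% y)
    sol <- solve(C, rhs)
    p <- ncol(X)
    beta <- sol[seq_len(p)]
    u <- sol[p + seq_len(n)]
    v <- matrix(sol[p + n + seq_len(n * l)], n, l,
                dimnames = list(design$line_ids, design$env_levels))
    names(u) <- design$line_ids
    fit <- new_met_fit(design, vc, beta, u, v, gebv = v + u,
                       loglik = restricted_loglik(design, vc, K),
                       method = "mme")
  } else {
    rinv <- rep(1 / vc$sigma_e2, N)
    Z <- matrix(0, N, n)
    Z[cbind(seq_len(N), i)] <- 1
    XtR <- t(X * rinv)
    ZtR <- t(Z * rinv)
    C <- rbind(cbind(XtR %*% X, XtR %*% Z),
               cbind(ZtR %*% X, ZtR %*% Z + Kinv / vc$sigma_g2))
    rhs <- c(XtR %*% y, ZtR %*% y)
    sol <- solve(C, rhs)
    p <- ncol(X)
    beta <- sol[seq_len(p)]
    u <- sol[-seq_len(p)]
    names(u) <- design$line_ids
    gebv <- matrix(u, n, 1, dimnames = list(design$line_ids,
                                            design$env_levels))
    fit <- new_met_fit(design, vc, beta, u, v = NULL, gebv = gebv,
                       loglik = restricted_loglik(design, vc, K),
                       method = "mme")
  }
  fit
}

## REML log-likelihood from a gls_solve() result
reml_ll_from_gls <- function(design, g) {
  N <- design$N
  X <- design$X
  p <- ncol(X)
  logdetV <- 2 * sum(log(diag(g$chV)))
  logdetXtViX <- determinant(g$XtViX, logarithm = TRUE)$modulus
  logdetXtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  rPr <- sum(g$resid * g$w)
  -0.5 * ((N - p) * log(2 * pi) + logdetV + as.numeric(logdetXtViX) -
            as.numeric(logdetXtX) + rPr)
}

#' Restricted log-likelihood of variance components
#'
#' Evaluates the REML log-likelihood of `vc` for the observed records of
#' `design`, defined as the log density of any orthonormal set of error
#' contrasts of y (the value is invariant to the choice of contrasts and to
#' the fixed-effect basis). Computed from the dense marginal covariance
#' V = Z G Z' + R of the observed records.
#'
#' @inheritParams solve_mme
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(design, vc, K) {
  g <- gls_solve(design, vc, K)
  reml_ll_from_gls(design, g)
}

#' Per-environment SNP heritability
#'
#' h2_e = sigma_g2 / (sigma_g2 + sigma_e2) with the environment's genetic and
#' residual variances: G0\[e,e\] / (G0\[e,e\] + R0\[e,e\]) under Model 1,
#' (sigma_g2 + sigma_v2) / (sigma_g2 + sigma_v2 + sigma_e2_e) under Model 2
#' (total genetic variance in the numerator) and
#' sigma_g2 / (sigma_g2 + sigma_e2) under Model 3.
#'
#' @param vc A [variance_components] object.
#' @param env Environment index (Models 1-2; ignored for Model 3).
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(vc, env = 1L) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$model == 1L) {
    g <- vc$G0[env, env]
    r <- build_covariance(vc$R0)[env, env]
  } else if (vc$model == 2L) {
    g <- vc$sigma_g2 + vc$sigma_v2
    r <- rep(vc$sigma_e2, length.out = max(env))[env]
  } else {
    g <- vc$sigma_g2
    r <- vc$sigma_e2
  }
  if (g + r <= 0) stop("zero total variance: heritability undefined")
  g / (g + r)
}

#' Genomic correlation between environments
#'
#' The correlation matrix of the Model 1 genetic covariance G0:
#' r_ij = G0_ij / sqrt(G0_ii G0_jj).
#'
#' @param vc Model 1 [variance_components].
#' @return l x l correlation matrix with unit diagonal.
#' @export
genomic_correlation <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$model != 1L) stop("genomic correlation is defined for Model 1")
  if (any(diag(vc$G0) <= 0))
    stop("zero genetic variance in some environment")
  stats::cov2cor(vc$G0)
}
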