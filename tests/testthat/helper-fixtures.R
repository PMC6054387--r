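# shared fixtures: small random instances built in code

# random symmetric positive-definite matrix
rand_pd <- function(l, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(l * l), l)
  crossprod(A) / l + diag(l)
}

# small well-conditioned kinship with line ids
rand_kinship <- function(n, seed = 1) {
  set.seed(seed)
  K <- crossprod(matrix(rnorm(n * n), n)) / n + diag(0.5, n)
  rownames(K) <- colnames(K) <- sprintf("L%03d", seq_len(n))
  K
}

# residual structure of a given kind with "typical" parameters
example_structure <- function(kind, l) {
  switch(kind,
    IDV = residual_structure("IDV", l, 1.3),
    IDH = residual_structure("IDH", l, seq(0.5, 2, length.out = l)),
    US = {
      S <- rand_pd(l, seed = 42)
      residual_structure("US", l, S[lower.tri(S, diag = TRUE)])
    },
    ANT1 = residual_structure(
      "ANT1", l, c(seq(0.8, 1.5, length.out = l),
                   rep(0.4, l - 1))))
}

# simulate a small complete MET instance; returns design, K, truth
small_met <- function(n = 6, l = 2, kind = "US", seed = 3,
                      missing_cells = NULL) {
  set.seed(seed)
  K <- rand_kinship(n, seed)
  G0 <- rand_pd(l, seed + 1)
  rs <- example_structure(kind, l)
  cfg <- sim_config(n, 10, l, G0, rs,
                    env_means = seq_len(l), seed = seed)
  sim <- simulate_met(cfg, K)
  ph <- sim$phenotypes
  if (!is.null(missing_cells)) ph$value[missing_cells] <- NA
  design <- build_design(ph, rownames(K), model = 1)
  list(design = design, K = K, G0 = G0, rs = rs, ph = ph, sim = sim)
}

# dense-oracle REML log-likelihood from orthonormal error contrasts of X,
# written independently of the package internals
oracle_reml_ll <- function(design, V) {
  X <- design$X
  y <- design$y
  qrX <- qr(X)
  Qc <- qr.Q(qrX, complete = TRUE)[, -seq_len(qrX$rank), drop = FALSE]
  S <- t(Qc) %*% V %*% Qc
  z <- drop(t(Qc) %*% y)
  -0.5 * (length(z) * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            drop(crossprod(z, solve(S, z))))
}

# dense-oracle marginal covariance and conditional mean of u given y for
# Model 1, via explicit Kronecker algebra
oracle_model1 <- function(design, G0, R0mat, K) {
  n <- design$n
  l <- design$l
  i <- design$line_idx
  e <- design$env_idx
  N <- design$N
  Z <- matrix(0, N, n * l)
  Z[cbind(seq_len(N), (e - 1L) * n + i)] <- 1
  G <- kronecker(G0, K)
  Rfull <- kronecker(R0mat, diag(n))
  idx <- (e - 1L) * n + i
  V <- Z %*% G %*% t(Z) + Rfull[idx, idx]
  X <- design$X
  y <- design$y
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- G %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(V = V, beta = drop(beta), u = matrix(u, n, l))
}
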