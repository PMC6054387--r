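#' Simulate biallelic SNP genotypes in linkage equilibrium
#'
#' Draws each marker's allele frequency uniformly on `allele_freq_range` and
#' each dosage as the sum of two Bernoulli(p_j) draws (Hardy-Weinberg
#' genotypes, independent markers). The default frequency range [0.05, 0.95]
#' mirrors a MAF > 0.05 marker filter.
#'
#' @param n_lines Number of lines (>= 2).
#' @param n_markers Number of markers (>= 1).
#' @param allele_freq_range Length-2 numeric in (0, 1).
#' @param seed Optional integer seed; identical seeds give identical matrices.
#' @return Dosage matrix from [marker_matrix()] with attribute `"freq"`
#'   holding the simulated allele frequencies.
#' @export
simulate_genotypes <- function(n_lines, n_markers,
                               allele_freq_range = c(0.05, 0.95),
                               seed = NULL) {
  if (n_lines < 2 || n_markers < 1)
    stop("need n_lines >= 2 and n_markers >= 1")
  stopifnot(length(allele_freq_range) == 2,
            all(allele_freq_range > 0), all(allele_freq_range < 1),
            allele_freq_range[1] <= allele_freq_range[2])
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(n_markers, allele_freq_range[1], allele_freq_range[2])
  g <- matrix(stats::rbinom(n_lines * n_markers, 2L, rep(p, each = n_lines)),
              nrow = n_lines, ncol = n_markers)
  mm <- marker_matrix(g,
                      line_ids = sprintf("L%04d", seq_len(n_lines)),
                      marker_ids = sprintf("M%05d", seq_len(n_markers)))
  attr(mm, "freq") <- p
  mm
}

#' Configuration of a synthetic multi-environment trial
#'
#' Collects the generative parameters of the MET model
#' y_ie = beta_e + u_ie + eps_ie with vec(u) ~ N(0, G0 (x) K) and residual
#' rows i.i.d. N(0, R0) across lines.
#'
#' @param n_lines,n_markers,n_env Dimensions (lines, markers, environments l).
#' @param G0 l x l symmetric positive semi-definite genetic covariance
#'   between environments (trait-variance units).
#' @param residual_structure A [residual_structure()] with `l = n_env`.
#' @param env_means Length-l vector of environment means beta (trait units).
#' @param allele_freq_range Marker allele-frequency range, see
#'   [simulate_genotypes()].
#' @param missing_fraction Fraction of phenotype cells set missing completely
#'   at random, in \[0, 1); no line is ever missing in all environments.
#' @param seed Integer seed driving all randomness of the simulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines, n_markers, n_env, G0, residual_structure,
                       env_means = rep(0, n_env),
                       allele_freq_range = c(0.05, 0.95),
                       missing_fraction = 0, seed = 1L) {
  stopifnot(n_lines >= 2, n_markers >= 1, n_env >= 1)
  G0 <- as.matrix(G0)
  if (!all(dim(G0) == n_env)) stop("G0 must be n_env x n_env")
  if (max(abs(G0 - t(G0))) > 1e-8 * max(abs(G0), 1))
    stop("G0 must be symmetric")
  G0 <- (G0 + t(G0)) / 2
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("G0 must be positive semi-definite")
  stopifnot(inherits(residual_structure, "residual_structure"),
            residual_structure$l == n_env,
            length(env_means) == n_env,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers),
                 n_env = as.integer(n_env), G0 = G0,
                 residual_structure = residual_structure,
                 env_means = as.numeric(env_means),
                 allele_freq_range = allele_freq_range,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## symmetric PSD square root (handles exactly singular, e.g. G0 = 0)
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate phenotypes of a multi-environment trial
#'
#' Generates y_ie = beta_e + u_ie + eps_ie for each line i and environment e.
#' Breeding values use a matrix-normal factorization: u = A Z B' with
#' A A' = K + 1e-8 I (Cholesky jitter against numerically singular K) and
#' B B' = G0, so that vec(u) ~ N(0, G0 (x) K). Residual rows are i.i.d.
#' N(0, R0) with R0 = `build_covariance(cfg$residual_structure)`. A
#' `missing_fraction` of cells is masked completely at random, re-drawn if a
#' mask would leave any line unobserved in every environment.
#'
#' @param cfg A [sim_config()].
#' @param kinship n x n kinship matrix K (e.g. from [compute_grm()]), or a
#'   prepared `kinship_eigen` object.
#' @return A list of class `sim_met` with `phenotypes` (long table with
#'   columns `line`, `env`, `value`, `observed`; `value` is `NA` where
#'   unobserved), `true_u` (n x l breeding values), `true_components`
#'   (list with `G0` and the residual structure), and `env_means`.
#' @export
simulate_met <- function(cfg, kinship) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(kinship, "kinship_eigen")) kinship <- kinship$K
  K <- as.matrix(kinship)
  n <- cfg$n_lines
  l <- cfg$n_env
  if (!all(dim(K) == n)) stop("kinship dimension must equal n_lines")
  set.seed(cfg$seed)
  A <- t(chol((K + t(K)) / 2 + diag(1e-8, n)))
  B <- psd_sqrt(cfg$G0)
  u <- A %*% matrix(stats::rnorm(n * l), n, l) %*% t(B)
  R0 <- build_covariance(cfg$residual_structure)
  eps <- matrix(stats::rnorm(n * l), n, l) %*% t(psd_sqrt(R0))
  y <- sweep(u + eps, 2, cfg$env_means, `+`)

  obs <- matrix(TRUE, n, l)
  n_miss <- floor(cfg$missing_fraction * n * l)
  if (n_miss > 0) {
    for (try in 1:1000) {
      cells <- sample.int(n * l, n_miss)
      m <- matrix(TRUE, n, l)
      m[cells] <- FALSE
      if (all(rowSums(m) > 0)) { obs <- m; break }
      if (try == 1000)
        stop("could not draw a missingness mask leaving every line observed")
    }
  }

  line_ids <- rownames(K)
  if (is.null(line_ids)) line_ids <- sprintf("L%04d", seq_len(n))
  env_ids <- sprintf("E%d", seq_len(l))
  pheno <- data.frame(
    line = rep(line_ids, times = l),
    env = rep(env_ids, each = n),
    value = ifelse(as.vector(obs), as.vector(y), NA_real_),
    observed = as.vector(obs),
    stringsAsFactors = FALSE)
  dimnames(u) <- list(line_ids, env_ids)
  structure(list(phenotypes = pheno, true_u = u,
                 true_components = list(
                   G0 = cfg$G0,
                   residual_structure = cfg$residual_structure),
                 env_means = stats::setNames(cfg$env_means, env_ids),
                 config = cfg),
            class = "sim_met")
}

#' Simulate a complete study: genotypes, kinship and phenotypes
#'
#' Convenience wrapper chaining [simulate_genotypes()], [compute_grm()] and
#' [simulate_met()] under a single seed.
#'
#' @inheritParams simulate_met
#' @return A `sim_met` list additionally carrying `genotypes` and `K`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  geno <- simulate_genotypes(cfg$n_lines, cfg$n_markers,
                             cfg$allele_freq_range, seed = cfg$seed)
  K <- compute_grm(geno)
  ## offset the phenotype seed so the genotype and phenotype draws never
  ## share a position in the random stream
  cfg_ph <- cfg
  cfg_ph$seed <- cfg$seed + 1L
  res <- simulate_met(cfg_ph, K)
  res$config <- cfg
  res$genotypes <- geno
  res$K <- K
  res
}
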