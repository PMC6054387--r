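#' Prior specification for the Bayesian MET models
#'
#' The genetic covariance G0 takes an inverse-Wishart prior with a diagonal
#' scale matrix (by default the per-environment univariate variance-component
#' estimates, the same device used to initialize REML) and degrees of freedom
#' l + 1 (weakly informative). The residual side is conjugate where possible:
#' inverse-Wishart for US; a scaled inverse chi-square per variance for IDV,
#' IDH and the ANT1 standard deviations; uniform(-1, 1) for the ANT1
#' adjacent correlations. Fixed effects get a vague zero-mean Gaussian prior
#' with a large variance.
#'
#' @param G0_scale l x l positive-definite scale matrix of the
#'   inverse-Wishart prior on G0 (Model 1).
#' @param G0_df Inverse-Wishart degrees of freedom, must exceed l - 1.
#' @param R0_scale US: l x l scale matrix; other kinds: vector of prior
#'   scale values s0^2 for the scaled inverse chi-square variance priors
#'   (recycled to length l).
#' @param R0_df US: inverse-Wishart degrees of freedom; other kinds: the
#'   inverse chi-square prior degrees of freedom (default 4, weakly
#'   informative with a finite mean).
#' @param var_scale,var_df Scale and degrees of freedom of the scaled
#'   inverse chi-square priors on scalar variances (sigma_g2, sigma_v2 and
#'   Model 2/3 residuals).
#' @param beta_var Prior variance of the fixed effects (>= 1e6).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(G0_scale = NULL, G0_df = NULL, R0_scale = NULL,
                       R0_df = NULL, var_scale = 1, var_df = 4,
                       beta_var = 1e8) {
  if (beta_var < 1e6) stop("beta prior variance must be vague (>= 1e6)")
  structure(list(G0_scale = G0_scale, G0_df = G0_df, R0_scale = R0_scale,
                 R0_df = R0_df, var_scale = var_scale, var_df = var_df,
                 beta_var = beta_var),
            class = "prior_spec")
}

## default priors from the per-environment univariate fits
default_prior <- function(design, K, model, structure_kind) {
  l <- design$l
  init <- init_from_univariate(design, K, model = 1L,
                               structure_kind = "IDH")
  univ <- attr(init, "univariate")
  sg <- pmax(univ$sigma_g2, 1e-6)
  se <- pmax(univ$sigma_e2, 1e-6)
  if (model == 1L) {
    pr <- prior_spec(G0_scale = diag(sg, l), G0_df = l + 1,
                     R0_scale = if (structure_kind == "US") diag(se, l)
                                else se,
                     R0_df = if (structure_kind == "US") l + 1 else 4,
                     var_scale = mean(se), var_df = 4)
  } else {
    pr <- prior_spec(R0_scale = se, R0_df = 4,
                     var_scale = mean(sg), var_df = 4)
  }
  pr$univariate <- univ
  pr
}

## inverse-Wishart draw: W^-1 with W ~ Wishart(df, scale^-1)
riwish <- function(df, S) {
  W <- stats::rWishart(1, df, solve(S))[, , 1]
  solve(W)
}

## scaled inverse chi-square posterior draw given prior (df0, s02) and a
## residual sum of squares over m observations
rinvchisq_post <- function(df0, s02, sse, m) {
  shape <- (df0 + m) / 2
  rate <- (df0 * s02 + sse) / 2
  rate / stats::rgamma(1, shape = shape)
}

dinvchisq_log <- function(x, df0, s02) {
  a <- df0 / 2
  b <- df0 * s02 / 2
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' Gibbs sampler for the Bayesian MET models
#'
#' Markov chain Monte Carlo over the fixed effects, breeding values and
#' variance parameters of Models 1-3. Fixed effects and breeding values are
#' drawn jointly from their Gaussian full conditional (fixed effects from
#' the marginal with breeding values integrated out, then breeding values
#' given them), working in the eigenbasis of K so every sweep costs
#' O(n l^2). G0 (Model 1) uses its conjugate inverse-Wishart full
#' conditional; sigma_g2/sigma_v2 (Models 2-3) and IDV/IDH residual
#' variances use scaled inverse chi-square full conditionals; the US
#' residual matrix uses inverse-Wishart; the ANT1 block uses
#' Metropolis-within-Gibbs on unconstrained coordinates with an adaptive
#' random-walk scale targeting 20-40 percent acceptance. Missing phenotype
#' cells (including whole held-out lines) are sampled from their Gaussian
#' full conditional each sweep (data augmentation), so predictions for
#' missing cells are posterior-predictive. Model 2 draws the total
#' per-environment genetic value and decomposes it into main and
#' interaction parts, whose variances are then updated conjugately.
#'
#' @inheritParams reml_fit
#' @param model 1, 2 or 3 (defaults to the design's model).
#' @param prior A [prior_spec()]; default built from univariate fits.
#' @param n_iter,burnin,thin Chain length, burn-in and thinning; draws kept
#'   are `(n_iter - burnin) / thin`.
#' @param seed Integer seed; identical seeds give identical chains.
#' @param fix Optional named list of parameters to hold fixed (supported:
#'   `sigma_g2` for Model 3), used for conjugate-update verification.
#' @return An object of class `posterior_chain`: `draws` (matrix of stored
#'   variance/fixed-effect draws, one named column per parameter, plus
#'   derived `h2_*` and `cor_*` columns for Model 1), `gebv_draws` (array
#'   stored x lines x environments of per-environment genomic values),
#'   iteration metadata, and the Metropolis acceptance rate for ANT1.
#' @export
run_mcmc <- function(design, K, model = design$model,
                     structure_kind = "US", prior = NULL,
                     n_iter = 10000, burnin = 3000, thin = 10,
                     seed = 1L, fix = NULL) {
  stopifnot(inherits(design, "met_design"))
  if (n_iter <= burnin) stop("`n_iter` must exceed `burnin`")
  l <- design$l
  n <- design$n
  if (model == 3L && l != 1L) stop("Model 3 designs are univariate")
  if (model == 2L) structure_kind <- match.arg(structure_kind,
                                               c("IDV", "IDH"))
  if (model == 1L) structure_kind <- match.arg(structure_kind,
                                               c("US", "IDH", "IDV", "ANT1"))
  eigK <- kinship_eigen(K_subset(K, design$line_ids))
  if (is.null(prior)) {
    if (design$N == 0)
      stop("no observed records: supply an explicit `prior`")
    prior <- default_prior(design, K, model, structure_kind)
  }
  if (model == 1L) {
    if (is.null(prior$G0_scale) || is.null(prior$G0_df))
      stop("Model 1 needs a G0 inverse-Wishart prior")
    if (prior$G0_df <= l - 1) stop("G0 prior df must exceed l - 1")
    if (structure_kind == "US" && prior$R0_df <= l - 1)
      stop("US residual prior df must exceed l - 1")
  }
  set.seed(seed)

  U <- eigK$U
  d <- eigK$d
  xtil <- drop(crossprod(U, rep(1, n)))
  Yobs <- matrix(NA_real_, n, l)
  Yobs[cbind(design$line_idx, design$env_idx)] <- design$y
  obs <- design$obs_mask
  ## lines grouped by missing pattern (fixed over the chain)
  pat_key <- apply(obs, 1, function(r) paste(which(!r), collapse = ","))
  patterns <- split(seq_len(n), pat_key)
  patterns <- patterns[names(patterns) != ""]

  bv <- prior$beta_var
  ## initial state: environment means and split phenotypic variances keep
  ## the chain away from the degenerate zero-variance corner
  beta <- vapply(seq_len(l), function(e) {
    v <- Yobs[obs[, e], e]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  v_init <- vapply(seq_len(l), function(e) {
    v <- Yobs[obs[, e], e]
    if (length(v) > 2 && stats::var(v) > 0) stats::var(v) else 1
  }, numeric(1))
  Y <- Yobs
  for (e in seq_len(l)) Y[!obs[, e], e] <- beta[e]
  A <- matrix(0, n, l)          # breeding values in the eigenbasis of K
  se0 <- rep(prior$R0_scale, length.out = l)
  if (model == 1L) {
    G0 <- diag(v_init / 2, l)
    R0 <- diag(v_init / 2, l)
    ant_theta <- if (structure_kind == "ANT1")
      c(0.5 * log(v_init / 2), rep(0, l - 1)) else NULL
  } else {
    sg2 <- mean(v_init) / 3
    sv2 <- mean(v_init) / 3
    se2 <- if (model == 2L && structure_kind == "IDH") v_init / 3
           else mean(v_init) / 3
    if (!is.null(fix$sigma_g2)) sg2 <- fix$sigma_g2
    if (model == 3L) R0 <- diag(se2[1], 1)
  }
  ant_scale <- 0.1
  ant_acc <- ant_try <- 0
  v_scale <- 0.15
  vs_acc <- vs_try <- 0
  n_keep <- (n_iter - burnin) %/% thin
  if (n_keep < 1) stop("no draws kept: check n_iter/burnin/thin")
  par_names <- mcmc_par_names(design, model, structure_kind)
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  gebv_draws <- array(NA_real_, c(n_keep, n, l),
                      dimnames = list(NULL, design$line_ids,
                                      design$env_levels))
  keep <- 0L

  for (it in seq_len(n_iter)) {
    ## current (G0, R0) pair on the environment scale
    if (model == 2L) {
      G0 <- matrix(sg2, l, l) + diag(sv2, l)
      R0 <- diag(rep(se2, length.out = l), l)
    } else if (model == 3L) {
      G0 <- matrix(sg2, 1, 1)
      R0 <- matrix(se2[1], 1, 1)
    }
    U_A <- U %*% A              # breeding values on the line scale

    ## 1) data augmentation of missing cells
    if (length(patterns)) {
      mu_full <- sweep(U_A, 2, beta, `+`)
      for (pi in seq_along(patterns)) {
        rows <- patterns[[pi]]
        M <- which(!obs[rows[1], ])
        O <- which(obs[rows[1], ])
        if (length(O) == 0) {
          cm <- mu_full[rows, M, drop = FALSE]
          cv <- R0
        } else {
          RooI <- solve(R0[O, O, drop = FALSE])
          H <- R0[M, O, drop = FALSE] %*% RooI
          epsO <- Y[rows, O, drop = FALSE] - mu_full[rows, O, drop = FALSE]
          cm <- mu_full[rows, M, drop = FALSE] + epsO %*% t(H)
          cv <- R0[M, M, drop = FALSE] - H %*% R0[O, M, drop = FALSE]
        }
        cv <- (cv + t(cv)) / 2
        Lc <- t(chol(cv + diag(1e-12, length(M))))
        Z <- matrix(stats::rnorm(length(rows) * length(M)),
                    length(rows), length(M))
        Y[rows, M] <- cm + Z %*% t(Lc)
      }
    }
    Ytil <- crossprod(U, Y)

    ## 2b) marginal Metropolis move on all variance parameters with the
    ## breeding values integrated out. Partially collapsed Gibbs: u is
    ## stale after this move, so it runs before beta and u are redrawn and
    ## nothing conditions on u until then. Cures the slow (u, variance)
    ## mixing of a purely conjugate sweep.
    if (model == 1L) {
      thG <- chol_log_theta(G0)
      thR <- r0_theta_kind(R0, structure_kind, l, ant_theta)
      thv <- c(thG, thR)
      free <- seq_along(thv)
      cur_lt <- marginal_var_ll(Ytil, xtil, d, beta, G0, R0) +
        liw(G0, prior$G0_df, prior$G0_scale) + logjac_chol_log(G0) +
        r0_log_prior(thR, structure_kind, l, prior)
      prop <- thv
      prop[free] <- thv[free] + v_scale * stats::rnorm(length(free))
      ng <- length(thG)
      G0p <- chol_log_matrix(prop[seq_len(ng)], l)
      R0p <- r0_from_theta_kind(prop[-seq_len(ng)], structure_kind, l)
      vs_try <- vs_try + 1
      if (all(is.finite(G0p)) && all(is.finite(R0p))) {
        cand_lt <- marginal_var_ll(Ytil, xtil, d, beta, G0p, R0p) +
          liw(G0p, prior$G0_df, prior$G0_scale) + logjac_chol_log(G0p) +
          r0_log_prior(prop[-seq_len(ng)], structure_kind, l, prior)
        if (is.finite(cand_lt) &&
            log(stats::runif(1)) < cand_lt - cur_lt) {
          G0 <- G0p
          R0 <- R0p
          if (structure_kind == "ANT1") ant_theta <- prop[-seq_len(ng)]
          vs_acc <- vs_acc + 1
        }
      }
    } else {
      thv <- if (model == 2L) c(log(sg2), log(sv2), log(se2))
             else c(log(sg2), log(se2[1]))
      free <- seq_along(thv)
      if (!is.null(fix$sigma_g2)) free <- free[-1]
      lp_fun <- function(th) {
        sg2c <- exp(th[1])
        if (model == 2L) {
          sv2c <- exp(th[2])
          se2c <- exp(th[-(1:2)])
          G0c <- matrix(sg2c, l, l) + diag(sv2c, l)
          R0c <- diag(rep(se2c, length.out = l), l)
          lp <- dinvchisq_log(sg2c, prior$var_df, prior$var_scale) +
            th[1] +
            dinvchisq_log(sv2c, prior$var_df, prior$var_scale) + th[2] +
            sum(dinvchisq_log(se2c, prior$R0_df,
                              rep(se0, length.out = length(se2c))[
                                seq_along(se2c)])) + sum(th[-(1:2)])
        } else {
          se2c <- exp(th[2])
          G0c <- matrix(sg2c, 1, 1)
          R0c <- matrix(se2c, 1, 1)
          lp <- dinvchisq_log(sg2c, prior$var_df, prior$var_scale) +
            th[1] + dinvchisq_log(se2c, prior$R0_df, se0[1]) + th[2]
        }
        marginal_var_ll(Ytil, xtil, d, beta, G0c, R0c) + lp
      }
      cur_lt <- lp_fun(thv)
      prop <- thv
      prop[free] <- thv[free] + v_scale * stats::rnorm(length(free))
      vs_try <- vs_try + 1
      cand_lt <- lp_fun(prop)
      if (is.finite(cand_lt) && log(stats::runif(1)) < cand_lt - cur_lt) {
        sg2 <- exp(prop[1])
        if (model == 2L) {
          sv2 <- exp(prop[2])
          se2 <- exp(prop[-(1:2)])
        } else se2 <- exp(prop[2])
        vs_acc <- vs_acc + 1
      }
    }
    if (it <= burnin && it %% 50 == 0 && vs_try > 0) {
      v_scale <- min(5, max(1e-3, v_scale * exp(vs_acc / vs_try - 0.25)))
      vs_acc <- vs_try <- 0
    }

    if (model == 2L) {
      G0 <- matrix(sg2, l, l) + diag(sv2, l)
      R0 <- diag(rep(se2, length.out = l), l)
    } else if (model == 3L) {
      G0 <- matrix(sg2, 1, 1)
      R0 <- matrix(se2[1], 1, 1)
    }


    ## simultaneous diagonalization of (G0, R0)
    Lr <- t(chol(R0))
    Bm <- forwardsolve(Lr, t(forwardsolve(Lr, G0)))
    eg <- eigen((Bm + t(Bm)) / 2, symmetric = TRUE)
    phi <- pmax(eg$values, 0)
    Q <- backsolve(t(Lr), eg$vectors)
    Qinv <- crossprod(eg$vectors, t(Lr))     # S' Lr'
    Wden <- 1 + outer(d, phi)

    ## 2) fixed effects from their marginal conditional (u integrated out)
    Tt <- Ytil %*% Q
    Aq <- colSums(xtil^2 / Wden)
    bq <- colSums(xtil * Tt / Wden)
    Prec <- Q %*% (Aq * t(Q)) + diag(1 / bv, l)
    bmean <- solve(Prec, Q %*% bq)
    Upc <- chol(Prec)
    beta <- drop(bmean + backsolve(Upc, stats::rnorm(l)))

    ## 3) breeding values given the fixed effects
    Rr <- Ytil - outer(xtil, beta)
    T2 <- Rr %*% Q
    Wt <- outer(d, phi) / Wden
    A <- (Wt * T2 + sqrt(Wt) * matrix(stats::rnorm(n * l), n, l)) %*% Qinv

    ## 4) variance components
    if (model == 1L) {
      Sg <- crossprod(A, A / d)
      G0 <- riwish(prior$G0_df + n, prior$G0_scale + Sg)
      E <- Y - outer(rep(1, n), beta) - U %*% A
      if (structure_kind == "US") {
        R0 <- riwish(prior$R0_df + n, prior$R0_scale + crossprod(E))
      } else if (structure_kind == "IDH") {
        s2 <- vapply(seq_len(l), function(e)
          rinvchisq_post(prior$R0_df, se0[e], sum(E[, e]^2), n), numeric(1))
        R0 <- diag(s2, l)
      } else if (structure_kind == "IDV") {
        s2 <- rinvchisq_post(prior$R0_df, mean(se0), sum(E^2), n * l)
        R0 <- diag(s2, l)
      } else { # ANT1: Metropolis on unconstrained coordinates
        EtE <- crossprod(E)
        lt <- function(th) ant1_log_target(th, EtE, n, prior, l)
        cur <- lt(ant_theta)
        prop <- ant_theta + ant_scale * stats::rnorm(2 * l - 1)
        cand <- lt(prop)
        ant_try <- ant_try + 1
        if (is.finite(cand) && log(stats::runif(1)) < cand - cur) {
          ant_theta <- prop
          ant_acc <- ant_acc + 1
        }
        if (it <= burnin && it %% 50 == 0 && ant_try > 0) {
          rate <- ant_acc / ant_try
          ant_scale <- min(10, max(1e-3,
                                   ant_scale * exp(rate - 0.3)))
          ant_acc <- ant_try <- 0
        }
        R0 <- build_covariance(inverse_transform(ant_theta, "ANT1", l))
      }
    } else {
      ## decompose the total genetic value into main + interaction
      if (model == 2L) {
        prec_u <- 1 / (sg2 * d) + l / (sv2 * d)
        mu_u <- (rowSums(A) / (sv2 * d)) / prec_u
        ut <- mu_u + stats::rnorm(n) / sqrt(prec_u)
        vt <- A - ut
        if (is.null(fix$sigma_g2))
          sg2 <- rinvchisq_post(prior$var_df, prior$var_scale,
                                sum(ut^2 / d), n)
        sv2 <- rinvchisq_post(prior$var_df, prior$var_scale,
                              sum(vt^2 / d), n * l)
        E <- Y - outer(rep(1, n), beta) - U %*% A
        if (structure_kind == "IDH") {
          se2 <- vapply(seq_len(l), function(e)
            rinvchisq_post(prior$R0_df, se0[e], sum(E[, e]^2), n),
            numeric(1))
        } else {
          se2 <- rep(rinvchisq_post(prior$R0_df, mean(se0), sum(E^2),
                                    n * l), 1)
        }
      } else { # model 3
        if (is.null(fix$sigma_g2))
          sg2 <- rinvchisq_post(prior$var_df, prior$var_scale,
                                sum(A[, 1]^2 / d), n)
        E <- Y - beta[1] - U %*% A
        se2 <- rinvchisq_post(prior$R0_df, se0[1], sum(E^2), n)
      }
    }

    ## 5) store
    if (it > burnin && (it - burnin) %% thin == 0) {
      keep <- keep + 1L
      draws[keep, ] <- mcmc_par_values(model, structure_kind, l, beta,
                                       G0, R0,
                                       if (model >= 2L) sg2 else NULL,
                                       if (model == 2L) sv2 else NULL,
                                       if (model >= 2L) se2 else NULL)
      gebv_draws[keep, , ] <- U %*% A
    }
  }

  structure(list(draws = draws[seq_len(keep), , drop = FALSE],
                 gebv_draws = gebv_draws[seq_len(keep), , , drop = FALSE],
                 model = model, structure_kind = structure_kind,
                 n_iter = n_iter, burnin = burnin, thin = thin,
                 seed = seed, prior = prior,
                 accept_rate = if (structure_kind == "ANT1" && ant_try > 0)
                   ant_acc / ant_try else NA_real_,
                 var_accept_rate = if (vs_try > 0) vs_acc / vs_try
                                   else NA_real_,
                 line_ids = design$line_ids,
                 env_levels = design$env_levels),
            class = "posterior_chain")
}

## ---- marginal variance-parameter move ------------------------------------
## Joint random-walk Metropolis on all variance parameters in unconstrained
## coordinates, targeting p(G0, R0 | Y, beta) with the breeding values
## integrated out analytically through the eigendecomposition of K. The
## conjugate per-block updates above leave the chain correct but can mix
## slowly through the (u, variance) funnel; this extra move (also a valid
## Gibbs step) restores fast mixing.

## log N(Ytil; xtil beta', sum_j [d_j G0 + R0]) in the eigenbasis of K
marginal_var_ll <- function(Ytil, xtil, d, beta, G0, R0) {
  n <- nrow(Ytil)
  l <- ncol(Ytil)
  Lr <- tryCatch(t(chol(R0)), error = function(e) NULL)
  if (is.null(Lr)) return(-Inf)
  Bm <- forwardsolve(Lr, t(forwardsolve(Lr, G0)))
  if (any(!is.finite(Bm))) return(-Inf)
  eg <- eigen((Bm + t(Bm)) / 2, symmetric = TRUE)
  phi <- pmax(eg$values, 0)
  Q <- backsolve(t(Lr), eg$vectors)
  T2 <- (Ytil - outer(xtil, beta)) %*% Q
  Wden <- 1 + outer(d, phi)
  -0.5 * (n * l * log(2 * pi) + 2 * n * sum(log(diag(Lr))) +
            sum(log(Wden)) + sum(T2^2 / Wden))
}

## log Jacobian of the log-diagonal Cholesky parameterization of an SPD
## matrix: |d vech(S) / d theta| = 2^l prod L_ii^(l - i + 2)
logjac_chol_log <- function(S) {
  L <- t(chol(S))
  l <- nrow(S)
  l * log(2) + sum((l - seq_len(l) + 2) * log(diag(L)))
}

## log inverse-Wishart density (unnormalized in the scale constant)
liw <- function(S, df, scale) {
  ch <- chol(S)
  ld <- 2 * sum(log(diag(ch)))
  -0.5 * ((df + nrow(S) + 1) * ld + sum(diag(scale %*% chol2inv(ch))))
}

## log prior of R0 in its unconstrained coordinates, incl. Jacobians
r0_log_prior <- function(theta, kind, l, prior) {
  se0 <- rep(prior$R0_scale, length.out = l)
  if (kind == "US") {
    R0 <- chol_log_matrix(theta, l)
    liw(R0, prior$R0_df, prior$R0_scale) + logjac_chol_log(R0)
  } else if (kind == "IDH") {
    s2 <- exp(theta)
    sum(dinvchisq_log(s2, prior$R0_df, se0)) + sum(theta)
  } else if (kind == "IDV") {
    s2 <- exp(theta)
    dinvchisq_log(s2, prior$R0_df, mean(se0)) + theta
  } else { # ANT1: inv-chi-square on variances, uniform correlations
    rs <- inverse_transform(theta, "ANT1", l)
    sig2 <- rs$params[seq_len(l)]^2
    lp <- sum(dinvchisq_log(sig2, prior$R0_df, se0)) + sum(log(2 * sig2))
    if (l > 1) {
      rho <- rs$params[(l + 1):(2 * l - 1)]
      lp <- lp + sum(log(1 - rho^2))
    }
    lp
  }
}

r0_from_theta_kind <- function(theta, kind, l) {
  if (kind == "US") chol_log_matrix(theta, l)
  else if (kind == "IDH") diag(exp(theta), l)
  else if (kind == "IDV") diag(rep(exp(theta), l), l)
  else build_covariance(inverse_transform(theta, "ANT1", l))
}

r0_theta_kind <- function(R0, kind, l, ant_theta = NULL) {
  if (kind == "US") chol_log_theta(R0)
  else if (kind == "IDH") log(diag(R0))
  else if (kind == "IDV") log(R0[1, 1])
  else ant_theta
}

## log full-conditional of the ANT1 parameters in unconstrained coordinates,
## including the transform Jacobians (inv-chi-square priors on the variances,
## uniform(-1,1) on the adjacent correlations)
ant1_log_target <- function(theta, EtE, n, prior, l) {
  rs <- inverse_transform(theta, "ANT1", l)
  R0 <- build_covariance(rs)
  ch <- tryCatch(chol(R0), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Rinv <- chol2inv(ch)
  ll <- -0.5 * (n * 2 * sum(log(diag(ch))) + sum(Rinv * EtE))
  sig2 <- rs$params[seq_len(l)]^2
  se0 <- rep(prior$R0_scale, length.out = l)
  lp <- sum(dinvchisq_log(sig2, prior$R0_df, se0)) + sum(log(2 * sig2))
  if (l > 1) {
    rho <- rs$params[(l + 1):(2 * l - 1)]
    lp <- lp + sum(log(1 - rho^2))    # uniform density constant dropped
  }
  ll + lp
}

mcmc_par_names <- function(design, model, kind) {
  l <- design$l
  env <- design$env_levels
  if (model == 1L) {
    ij <- which(lower.tri(diag(l), diag = TRUE), arr.ind = TRUE)
    g0n <- sprintf("g0_%d_%d", ij[, 1], ij[, 2])
    r0n <- switch(kind,
      US = sprintf("r0_%d_%d", ij[, 1], ij[, 2]),
      IDH = sprintf("r0_sigma2_%d", seq_len(l)),
      IDV = "r0_sigma2",
      ANT1 = c(sprintf("r0_sigma_%d", seq_len(l)),
               if (l > 1) sprintf("r0_rho_%d", seq_len(l - 1))))
    h2n <- sprintf("h2_%d", seq_len(l))
    corn <- if (l > 1) {
      od <- which(lower.tri(diag(l)), arr.ind = TRUE)
      sprintf("cor_%d_%d", od[, 1], od[, 2])
    } else character(0)
    c(paste0("beta_", env), g0n, r0n, h2n, corn)
  } else if (model == 2L) {
    c(paste0("beta_", env), "sigma_g2", "sigma_v2",
      if (kind == "IDH") sprintf("sigma_e2_%d", seq_len(l)) else "sigma_e2")
  } else {
    c("beta", "sigma_g2", "sigma_e2")
  }
}

mcmc_par_values <- function(model, kind, l, beta, G0, R0, sg2, sv2, se2) {
  if (model == 1L) {
    r0p <- switch(kind,
      US = sym_to_vech(R0),
      IDH = diag(R0),
      IDV = R0[1, 1],
      ANT1 = {
        sig <- sqrt(diag(R0))
        rho <- if (l > 1)
          vapply(seq_len(l - 1), function(k)
            R0[k, k + 1] / (sig[k] * sig[k + 1]), numeric(1))
        c(sig, rho)
      })
    h2 <- diag(G0) / (diag(G0) + diag(R0))
    corv <- if (l > 1) stats::cov2cor(G0)[lower.tri(diag(l))] else numeric(0)
    c(beta, sym_to_vech(G0), r0p, h2, corv)
  } else if (model == 2L) {
    c(beta, sg2, sv2, if (kind == "IDH") se2 else se2[1])
  } else {
    c(beta, sg2, se2[1])
  }
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf(
    "<posterior_chain model %d %s: %d stored draws (%d iters, burn-in %d, thin %d)>\n",
    x$model, x$structure_kind, nrow(x$draws), x$n_iter, x$burnin, x$thin))
  invisible(x)
}

#' Posterior mode of a scalar parameter from MCMC draws
#'
#' The maximizer of a Gaussian-kernel density estimate (Silverman's
#' rule-of-thumb bandwidth) over the stored marginal draws. With multiple
#' equal density maxima the first (lowest-value) grid maximum is returned.
#'
#' @param chain A [run_mcmc()] result.
#' @param parameter Column name of `chain$draws` (e.g. `"g0_1_1"`,
#'   `"sigma_e2"`, `"h2_2"`).
#' @return The estimated posterior mode (scalar).
#' @export
posterior_mode <- function(chain, parameter) {
  stopifnot(inherits(chain, "posterior_chain"))
  x <- chain$draws[, parameter]
  if (length(x) < 50) stop("need at least 50 stored draws")
  if (stats::sd(x) < 1e-12 * (abs(mean(x)) + 1e-12)) return(mean(x))
  dd <- stats::density(x, bw = "nrd0")
  dd$x[which.max(dd$y)]
}

#' Posterior-mean genomic values per line and environment
#'
#' The pointwise posterior mean of the per-environment genomic value draws
#' (breeding value u for Models 1 and 3; total u + v_e for Model 2), the
#' summary used for correlation-based prediction ability.
#'
#' @param chain A [run_mcmc()] result.
#' @return n x l matrix of posterior-mean GEBVs.
#' @export
point_gebv <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  out <- apply(chain$gebv_draws, c(2, 3), mean)
  matrix(out, dim(chain$gebv_draws)[2], dim(chain$gebv_draws)[3],
         dimnames = list(chain$line_ids, chain$env_levels))
}
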