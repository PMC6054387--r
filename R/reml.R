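## ---- unconstrained parameter packing shared by REML and the MH updates ----

## model 1: c(chol-log of G0, unconstrained R0 params)
## model 2: c(log sigma_g2, log sigma_v2, log sigma_e2 [1 or l])
## model 3: c(log sigma_g2, log sigma_e2)
theta_from_vc <- function(vc) {
  if (vc$model == 1L) {
    c(chol_log_theta(vc$G0), unconstrained_transform(vc$R0))
  } else if (vc$model == 2L) {
    c(log(vc$sigma_g2), log(vc$sigma_v2), log(vc$sigma_e2))
  } else {
    c(log(vc$sigma_g2), log(vc$sigma_e2))
  }
}

vc_from_theta <- function(theta, model, kind, l) {
  if (model == 1L) {
    ng <- (l * (l + 1L)) %/% 2L
    G0 <- chol_log_matrix(theta[seq_len(ng)], l)
    R0 <- inverse_transform(theta[-seq_len(ng)], kind, l)
    vc_model1(G0, R0)
  } else if (model == 2L) {
    ne <- length(theta) - 2L
    vc_model2(exp(theta[1]), exp(theta[2]), exp(theta[2 + seq_len(ne)]))
  } else {
    vc_model3(exp(theta[1]), exp(theta[2]))
  }
}

n_theta <- function(model, kind, l) {
  if (model == 1L) (l * (l + 1L)) %/% 2L + param_count(kind, l)
  else if (model == 2L) 2L + if (identical(kind, "IDH")) l else 1L
  else 2L
}

## (G0, R0) matrices implied by theta, without the vc wrapper (model 1/2/3
## all reduce to an l x l pair for the balanced-likelihood path; model 2 has
## compound-symmetric G0 = sigma_g2 J + sigma_v2 I)
theta_to_G0R0 <- function(theta, model, kind, l) {
  if (model == 1L) {
    ng <- (l * (l + 1L)) %/% 2L
    list(G0 = chol_log_matrix(theta[seq_len(ng)], l),
         R0 = build_covariance(inverse_transform(theta[-seq_len(ng)],
                                                 kind, l)))
  } else if (model == 2L) {
    se <- rep(exp(theta[-(1:2)]), length.out = l)
    list(G0 = matrix(exp(theta[1]), l, l) + diag(exp(theta[2]), l),
         R0 = diag(se, l))
  } else {
    list(G0 = matrix(exp(theta[1]), 1, 1), R0 = matrix(exp(theta[2]), 1, 1))
  }
}

## ---- balanced-data restricted likelihood via the eigendecomposition of K --

## One-time transforms for a complete design: phenotype matrix rotated by U'
## and the rotated intercept. Requires every (line, env) cell observed.
balanced_context <- function(design, eigK) {
  stopifnot(design_is_complete(design))
  n <- design$n
  l <- design$l
  Y <- matrix(NA_real_, n, l)
  Y[cbind(design$line_idx, design$env_idx)] <- design$y
  list(n = n, l = l,
       Ytil = crossprod(eigK$U, Y),
       xtil = drop(crossprod(eigK$U, rep(1, n))),
       d = eigK$d)
}

## REML log-likelihood at (G0, R0) for a complete layout; equals
## restricted_loglik() on the same data (the fixed-effect column space of all
## three models is the span of the environment intercepts).
balanced_reml_ll <- function(ctx, G0, R0) {
  n <- ctx$n
  l <- ctx$l
  Lr <- tryCatch(t(chol(R0)), error = function(e) NULL)
  if (is.null(Lr)) return(-Inf)
  B <- forwardsolve(Lr, t(forwardsolve(Lr, G0)))
  if (any(!is.finite(B))) return(-Inf)   # overflow at extreme variance ratios
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  phi <- pmax(eg$values, 0)
  Q <- backsolve(t(Lr), eg$vectors)
  T <- ctx$Ytil %*% Q
  Wden <- 1 + outer(ctx$d, phi)
  sumlogLr <- sum(log(diag(Lr)))
  logdetV <- 2 * n * sumlogLr + sum(log(Wden))
  Ak <- colSums(ctx$xtil^2 / Wden)
  bq <- colSums(ctx$xtil * T / Wden)          # Q' (X'V^-1 y) coordinates
  logdetXtViX <- sum(log(Ak)) - 2 * sumlogLr
  yViy <- sum(T^2 / Wden)
  rPr <- yViy - sum(bq^2 / Ak)
  N <- n * l
  -0.5 * ((N - l) * log(2 * pi) + logdetV + logdetXtViX - l * log(n) + rPr)
}

## ---- REML driver ----------------------------------------------------------

#' Variance components by univariate fits, for initialization and priors
#'
#' Fits the univariate GBLUP (Model 3) to each environment separately by
#' REML and assembles starting values for the multivariate models:
#' the Model 1 genetic covariance starts at the univariate genetic variances
#' on the diagonal with off-diagonals 0.5 * sqrt(sg_i * sg_j), and the
#' residual structure starts from the univariate residual variances
#' (averaged for IDV, per-environment for IDH/US/ANT1, zero initial
#' correlations). A degenerate environment (near-constant phenotype) falls
#' back to halving the pooled phenotypic variance, with a message.
#'
#' @inheritParams solve_mme
#' @param model Target model (1, 2 or 3) for which to assemble the start.
#' @param structure_kind Residual structure of the target model.
#' @return A [variance_components] object; the per-environment univariate
#'   estimates are attached as attribute `"univariate"`.
#' @export
init_from_univariate <- function(design, K, model = design$model,
                                 structure_kind = "US") {
  stopifnot(inherits(design, "met_design"))
  l <- design$l
  K <- as_kinship(K, design$line_ids)
  sg <- se <- numeric(l)
  vy_pool <- stats::var(design$y)
  for (eidx in seq_len(l)) {
    rows <- which(design$env_idx == eidx)
    ye <- design$y[rows]
    lines_e <- design$line_ids[design$line_idx[rows]]
    if (length(ye) < 3 || stats::var(ye) < 1e-10 * max(vy_pool, 1e-10)) {
      message("environment ", design$env_levels[eidx],
              " is degenerate; falling back to variance halving")
      sg[eidx] <- se[eidx] <- max(vy_pool / 2, 1e-6)
      next
    }
    ph <- data.frame(line = lines_e, env = design$env_levels[eidx],
                     value = ye, stringsAsFactors = FALSE)
    d3 <- build_design(ph, line_ids = lines_e, model = 3)
    Ke <- K[lines_e, lines_e]
    v0 <- stats::var(ye) / 2
    r <- reml_core(d3, Ke, kind = "IDV",
                   theta0 = log(c(v0, v0)), tol = 1e-8, max_iter = 100)
    vcs <- vc_from_theta(r$theta, 3L, "IDV", 1L)
    sg[eidx] <- vcs$sigma_g2
    se[eidx] <- vcs$sigma_e2
  }
  univ <- list(sigma_g2 = stats::setNames(sg, design$env_levels),
               sigma_e2 = stats::setNames(se, design$env_levels))
  out <- assemble_init(sg, se, model, structure_kind, l)
  attr(out, "univariate") <- univ
  out
}

## starting variance components from per-environment univariate estimates
assemble_init <- function(sg, se, model, structure_kind, l) {
  sg <- pmax(sg, 1e-8)
  se <- pmax(se, 1e-8)
  if (model == 1L) {
    G0 <- 0.5 * sqrt(outer(sg, sg))
    diag(G0) <- sg
    R0 <- switch(structure_kind,
      IDV = residual_structure("IDV", l, mean(se)),
      IDH = residual_structure("IDH", l, se),
      US  = residual_structure("US", l, sym_to_vech(diag(se, l))),
      ANT1 = residual_structure("ANT1", l, c(sqrt(se), rep(0, l - 1))))
    vc_model1(G0, R0)
  } else if (model == 2L) {
    sg2 <- max(mean(sg) / 2, 1e-8)
    if (identical(structure_kind, "IDH")) vc_model2(sg2, sg2, se)
    else vc_model2(sg2, sg2, mean(se))
  } else {
    vc_model3(sg[1], se[1])
  }
}

#' REML estimation of MET variance components
#'
#' Maximizes the restricted log-likelihood over the unconstrained transform
#' of the variance parameters (log variances, Fisher-z correlations,
#' log-diagonal Cholesky for unstructured matrices), so estimates never
#' leave the positive-definite set. Two quasi-Newton routes share this
#' parameterization: complete layouts (every line observed in every
#' environment) use BFGS on a fast likelihood evaluated through the
#' eigendecomposition of K; incomplete layouts use average-information REML
#' with step-halving on the dense marginal covariance. All four residual
#' structures are supported for Model 1, IDV/IDH for Model 2.
#'
#' @inheritParams solve_mme
#' @param structure_kind Residual covariance kind: `"US"`, `"IDH"`, `"IDV"`
#'   or `"ANT1"` (Model 1); `"IDV"` or `"IDH"` (Model 2); ignored for
#'   Model 3.
#' @param init Optional [variance_components] start; default
#'   [init_from_univariate()].
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap; hitting it sets `converged = FALSE`
#'   without error.
#' @return An object of class `reml_result`: `vc_hat`, `loglik`,
#'   `converged`, `n_iter`, `grad_norm` and `fit` (a [solve_mme()] result at
#'   the estimate).
#' @export
reml_fit <- function(design, K, structure_kind = "US", init = NULL,
                     tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(design, "met_design"))
  model <- design$model
  l <- design$l
  if (model == 2L) structure_kind <- match.arg(structure_kind, c("IDV", "IDH"))
  else if (model == 1L)
    structure_kind <- match.arg(structure_kind, c("US", "IDH", "IDV", "ANT1"))
  if (is.null(init))
    init <- init_from_univariate(design, K, model, structure_kind)
  theta0 <- theta_from_vc(init)
  if (length(theta0) != n_theta(model, structure_kind, l))
    stop("`init` does not match the requested model/structure")
  res <- reml_core(design, K, structure_kind, theta0, tol, max_iter)
  vc_hat <- vc_from_theta(res$theta, model, structure_kind, l)
  fit <- solve_mme(design, vc_hat, K)
  structure(list(vc_hat = vc_hat, loglik = res$loglik,
                 converged = res$converged, n_iter = res$n_iter,
                 grad_norm = res$grad_norm, init = init, fit = fit,
                 structure_kind = structure_kind, model = model),
            class = "reml_result")
}

#' @export
print.reml_result <- function(x, ...) {
  cat(sprintf(
    "<reml_result model %d %s: loglik %.4f, %s in %d iterations>\n",
    x$model, x$structure_kind, x$loglik,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

## dispatch between the balanced fast path and the dense AI path
reml_core <- function(design, K, kind, theta0, tol, max_iter) {
  model <- design$model
  l <- design$l
  if (design_is_complete(design)) {
    eigK <- kinship_eigen(K_subset(K, design$line_ids))
    ctx <- balanced_context(design, eigK)
    nll <- function(theta) {
      gr <- theta_to_G0R0(theta, model, kind, l)
      if (any(!is.finite(gr$G0)) || any(!is.finite(gr$R0))) return(1e10)
      v <- -balanced_reml_ll(ctx, gr$G0, gr$R0)
      if (!is.finite(v)) 1e10 else v   # soft barrier for the line search
    }
    if (nll(theta0) >= 1e10)
      stop("restricted likelihood is not finite at the initial values")
    grad <- function(theta) cfd_grad(nll, theta)
    opt <- stats::optim(theta0, nll, grad, method = "BFGS",
                        control = list(maxit = max_iter, reltol = tol))
    gtol <- function(ll) 1e-5 * (1 + abs(ll))   # scale-aware gradient rule
    g <- grad(opt$par)
    if (opt$convergence == 0 && max(abs(g)) >= gtol(-opt$value)) {
      # polish: the function-change rule can stop before the gradient
      # criterion is met along flat directions
      opt2 <- stats::optim(opt$par, nll, grad, method = "BFGS",
                           control = list(maxit = max_iter,
                                          reltol = 1e-14))
      if (opt2$value <= opt$value) {
        opt2$counts <- opt$counts + opt2$counts
        opt <- opt2
        g <- grad(opt$par)
      }
    }
    list(theta = opt$par, loglik = -opt$value,
         converged = opt$convergence == 0 && max(abs(g)) < gtol(-opt$value),
         n_iter = opt$counts[["function"]], grad_norm = max(abs(g)))
  } else {
    ai_reml(design, K, kind, theta0, tol, max_iter)
  }
}

K_subset <- function(K, line_ids) {
  if (inherits(K, "kinship_eigen")) {
    if (identical(K$ids, line_ids)) return(K)
    K <- K$K
  }
  as_kinship(K, line_ids)
}

## central finite differences (used on the cheap balanced likelihood and on
## the V(theta) map; the likelihood itself is smooth in theta)
cfd_grad <- function(f, theta, h = 1e-5) {
  vapply(seq_along(theta), function(k) {
    hp <- h * (1 + abs(theta[k]))
    tp <- tm <- theta
    tp[k] <- tp[k] + hp
    tm[k] <- tm[k] - hp
    (f(tp) - f(tm)) / (2 * hp)
  }, numeric(1))
}

## Average-information REML on unconstrained coordinates with step-halving;
## handles arbitrary missing-cell patterns through the dense marginal
## covariance of the observed records.
ai_reml <- function(design, K, kind, theta0, tol, max_iter) {
  model <- design$model
  l <- design$l
  K <- K_subset(K, design$line_ids)
  X <- design$X
  y <- design$y
  N <- design$N
  p <- ncol(X)
  Vfun <- function(theta)
    build_V(design, vc_from_theta(theta, model, kind, l), K)
  llfun <- function(V) {
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    ViX <- backsolve(ch, forwardsolve(t(ch), X))
    Viy <- backsolve(ch, forwardsolve(t(ch), y))
    XtViX <- crossprod(X, ViX)
    beta <- solve(XtViX, crossprod(X, Viy))
    r <- y - X %*% beta
    w <- backsolve(ch, forwardsolve(t(ch), r))
    ll <- -0.5 * ((N - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                    as.numeric(determinant(XtViX, TRUE)$modulus) -
                    as.numeric(determinant(crossprod(X), TRUE)$modulus) +
                    sum(r * w))
    list(ll = ll, ch = ch, ViX = ViX, XtViX = XtViX, Py = w)
  }
  theta <- theta0
  V <- Vfun(theta)
  cur <- llfun(V)
  if (!is.finite(cur$ll))
    stop("restricted likelihood is not finite at the initial values")
  k <- length(theta)
  n_iter <- 0L
  grad <- rep(Inf, k)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    Vi <- chol2inv(cur$ch)
    P <- Vi - cur$ViX %*% solve(cur$XtViX, t(cur$ViX))
    Py <- cur$Py
    Wm <- matrix(0, N, k)
    grad <- numeric(k)
    for (j in seq_len(k)) {
      hp <- 1e-6 * (1 + abs(theta[j]))
      tp <- tm <- theta
      tp[j] <- tp[j] + hp
      tm[j] <- tm[j] - hp
      dV <- (Vfun(tp) - Vfun(tm)) / (2 * hp)
      grad[j] <- -0.5 * (sum(P * dV) - drop(crossprod(Py, dV %*% Py)))
      Wm[, j] <- dV %*% Py
    }
    AI <- 0.5 * crossprod(Wm, P %*% Wm)
    ridge <- 1e-8 * max(diag(AI), 1)
    step <- tryCatch(solve(AI + diag(ridge, k), grad),
                     error = function(e) grad / max(diag(AI), 1))
    improved <- FALSE
    s <- 1
    for (half in 1:25) {
      cand_theta <- theta + s * step
      cand <- llfun(Vfun(cand_theta))
      if (is.finite(cand$ll) && cand$ll >= cur$ll - 1e-12) {
        improved <- TRUE
        break
      }
      s <- s / 2
    }
    if (!improved) break
    delta <- cand$ll - cur$ll
    theta <- cand_theta
    cur <- cand
    if (abs(delta) < tol * (abs(cur$ll) + 1) &&
        max(abs(grad)) < 1e-5 * (1 + abs(cur$ll))) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, loglik = cur$ll, converged = converged,
       n_iter = n_iter, grad_norm = max(abs(grad)))
}
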