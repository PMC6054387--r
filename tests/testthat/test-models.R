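test_that("design matrices follow the three model layouts", {
  ph <- expand.grid(line = c("A", "B", "C"), env = c("E1", "E2"),
                    stringsAsFactors = FALSE)
  ph$value <- rnorm(6)
  d1 <- build_design(ph, c("A", "B", "C"), model = 1)
  # block-diagonal of ones-vectors: one intercept per environment
  expect_identical(dim(d1$X), c(6L, 2L))
  expect_equal(unname(d1$X), rbind(cbind(rep(1, 3), 0), cbind(0, rep(1, 3))))

  ph3 <- expand.grid(line = sprintf("L%02d", 1:5), env = paste0("E", 1:3),
                     stringsAsFactors = FALSE)
  ph3$value <- rnorm(15)
  d2 <- build_design(ph3, sprintf("L%02d", 1:5), model = 2)
  # grand mean + l environment effects, one dropped by the sum-to-zero
  # constraint; the unconstrained count is 1 + l
  expect_identical(ncol(d2$X), 3L)
  expect_identical(attr(d2$X, "n_cols_unconstrained"), 4L)
  expect_true(all(d2$X[, 1] == 1))
  expect_identical(qr(d2$X)$rank, 3L)

  d3 <- build_design(ph3[ph3$env == "E2", ], sprintf("L%02d", 1:5),
                     model = 3)
  expect_identical(ncol(d3$X), 1L)
  expect_error(build_design(ph3, sprintf("L%02d", 1:5), model = 3),
               "univariate")
})

test_that("missing cells drop rows but keep all lines in the random term", {
  ph <- expand.grid(line = c("A", "B", "C"), env = c("E1", "E2"),
                    stringsAsFactors = FALSE)
  ph$value <- rnorm(6)
  ph$value[2] <- NA  # line B in E1
  d <- build_design(ph, c("A", "B", "C"), model = 1)
  expect_identical(d$N, 5L)
  expect_identical(d$n, 3L)
  expect_false(d$obs_mask["B", "E1"])
  expect_true(all(d$obs_mask[, "E2"]))

  expect_error(build_design(rbind(ph, ph[1, ]), c("A", "B", "C")),
               "duplicate")
  expect_error(build_design(ph, c("A", "B")), "absent")
  expect_error(build_design(ph, c("A", "B", "C"), env_levels = "E1"),
               "unknown environment")
})

test_that("solve_mme equals the dense conditional-mean oracle", {
  for (kind in c("US", "IDH", "IDV", "ANT1")) {
    inst <- small_met(n = 6, l = 3, kind = kind, seed = 10,
                      missing_cells = c(2, 9, 14))
    vc <- vc_model1(inst$G0, inst$rs)
    fit <- solve_mme(inst$design, vc, inst$K)
    orc <- oracle_model1(inst$design, inst$G0, build_covariance(inst$rs),
                         inst$K)
    expect_lt(max(abs(fit$u_hat - orc$u)), 1e-8)
    expect_lt(max(abs(fit$beta_hat - orc$beta)), 1e-8)
  }
})

test_that("Henderson and GLS routes agree", {
  inst <- small_met(n = 8, l = 2, kind = "US", seed = 21,
                    missing_cells = c(3, 12))
  vc <- vc_model1(inst$G0, inst$rs)
  f1 <- solve_mme(inst$design, vc, inst$K, method = "gls")
  f2 <- solve_mme(inst$design, vc, inst$K, method = "mme")
  expect_lt(max(abs(f1$u_hat - f2$u_hat)), 1e-6)
  expect_lt(max(abs(f1$beta_hat - f2$beta_hat)), 1e-6)

  d2 <- build_design(inst$ph, rownames(inst$K), model = 2)
  vc2 <- vc_model2(0.7, 0.3, 1.1)
  g1 <- solve_mme(d2, vc2, inst$K, method = "gls")
  g2 <- solve_mme(d2, vc2, inst$K, method = "mme")
  expect_lt(max(abs(g1$gebv - g2$gebv)), 1e-6)
  expect_equal(g2$gebv, g2$v_hat + g2$u_hat, tolerance = 1e-12)
})

test_that("restricted likelihood equals the orthonormal-contrast oracle", {
  inst <- small_met(n = 8, l = 2, kind = "ANT1", seed = 33,
                    missing_cells = c(5))
  vc <- vc_model1(inst$G0, inst$rs)
  V <- metGBLUP:::build_V(inst$design, vc, inst$K)
  expect_equal(restricted_loglik(inst$design, vc, inst$K),
               oracle_reml_ll(inst$design, V), tolerance = 1e-8)
})

test_that("restricted likelihood is invariant to line relabelling", {
  inst <- small_met(n = 7, l = 2, kind = "US", seed = 40)
  vc <- vc_model1(inst$G0, inst$rs)
  ll <- restricted_loglik(inst$design, vc, inst$K)
  set.seed(1)
  perm <- sample(7)
  ids <- rownames(inst$K)[perm]
  Kp <- inst$K[perm, perm]
  dp <- build_design(inst$ph, ids, model = 1)
  expect_equal(restricted_loglik(dp, vc, Kp), ll, tolerance = 1e-10)
})

test_that("rescaling data and variances shifts the likelihood by the exact
           Jacobian term", {
  inst <- small_met(n = 6, l = 2, kind = "IDH", seed = 55)
  vc <- vc_model1(inst$G0, inst$rs)
  ll <- restricted_loglik(inst$design, vc, inst$K)
  cc <- 2.5
  ph2 <- inst$ph
  ph2$value <- cc * ph2$value
  d2 <- build_design(ph2, rownames(inst$K), model = 1)
  vc2 <- vc_model1(cc^2 * inst$G0,
                   residual_structure("IDH", 2, cc^2 * inst$rs$params))
  ll2 <- restricted_loglik(d2, vc2, inst$K)
  # error contrasts live in N - p dimensions, so the change of variables
  # y -> c y contributes -(N - p) log c
  Np <- inst$design$N - ncol(inst$design$X)
  expect_equal(ll2 - ll, -Np * log(cc), tolerance = 1e-8)
})

test_that("Model 2 equals Model 1 with compound-symmetric G0", {
  inst <- small_met(n = 10, l = 3, kind = "IDV", seed = 61)
  sg <- 0.8; sv <- 0.35; se <- 1.2
  d2 <- build_design(inst$ph, rownames(inst$K), model = 2)
  f2 <- solve_mme(d2, vc_model2(sg, sv, se), inst$K)
  G0cs <- matrix(sg, 3, 3) + diag(sv, 3)
  f1 <- solve_mme(inst$design, vc_model1(G0cs,
                                         residual_structure("IDV", 3, se)),
                  inst$K)
  expect_lt(max(abs(f1$gebv - f2$gebv)), 1e-6)
})

test_that("infinite shrinkage sends breeding values to zero and BLUEs to
           GLS environment means", {
  inst <- small_met(n = 9, l = 2, kind = "IDV", seed = 72)
  vc <- vc_model1(diag(1e-12, 2), inst$rs)
  fit <- solve_mme(inst$design, vc, inst$K)
  expect_lt(max(abs(fit$u_hat)), 1e-9)
  # with G ~ 0 and IDV residual, the GLS means are the arithmetic means
  ym <- tapply(inst$design$y, inst$design$env_idx, mean)
  expect_equal(unname(fit$beta_hat), as.numeric(ym), tolerance = 1e-6)
})

test_that("GEBV norm shrinks monotonically as residual variance grows", {
  inst <- small_met(n = 8, l = 2, kind = "IDV", seed = 81)
  norms <- vapply(c(0.5, 2, 8, 32), function(s2) {
    fit <- solve_mme(inst$design,
                     vc_model1(inst$G0, residual_structure("IDV", 2, s2)),
                     inst$K)
    sqrt(sum(fit$u_hat^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("Model 3 with identity kinship is ridge regression", {
  n <- 20
  set.seed(5)
  y <- rnorm(n, mean = 3)
  ids <- sprintf("L%02d", 1:n)
  K <- diag(n); rownames(K) <- colnames(K) <- ids
  ph <- data.frame(line = ids, env = "E1", value = y)
  d <- build_design(ph, ids, model = 3)
  sg <- 0.7; se <- 1.4
  fit <- solve_mme(d, vc_model3(sg, se), K)
  # closed form: beta = mean(y), u = (sg/(sg+se)) (y - mean)
  expect_equal(unname(fit$beta_hat), mean(y), tolerance = 1e-8)
  expect_equal(unname(fit$u_hat), sg / (sg + se) * (y - mean(y)),
               tolerance = 1e-8)
})

test_that("with one environment Models 1 and 3 coincide", {
  n <- 12
  K <- rand_kinship(n, 91)
  set.seed(92)
  ph <- data.frame(line = rownames(K), env = "E1",
                   value = rnorm(n, 2))
  d1 <- build_design(ph, rownames(K), model = 1)
  d3 <- build_design(ph, rownames(K), model = 3)
  sg <- 0.9; se <- 0.6
  f1 <- solve_mme(d1, vc_model1(matrix(sg, 1, 1),
                                residual_structure("IDV", 1, se)), K)
  f3 <- solve_mme(d3, vc_model3(sg, se), K)
  expect_lt(max(abs(f1$gebv - f3$gebv)), 1e-8)
  expect_equal(restricted_loglik(d1, vc_model1(matrix(sg, 1, 1),
                                 residual_structure("IDV", 1, se)), K),
               restricted_loglik(d3, vc_model3(sg, se), K),
               tolerance = 1e-10)
})

test_that("heritability and genomic correlation follow their formulas", {
  expect_equal(heritability(vc_model3(1, 1)), 0.5)
  expect_equal(heritability(vc_model3(3, 1)), 0.75)
  expect_equal(heritability(vc_model3(1e-12, 1)), 0, tolerance = 1e-10)
  vc1 <- vc_model1(diag(c(1, 2)), residual_structure("IDH", 2, c(1, 2)))
  expect_equal(heritability(vc1, 1), 0.5)
  expect_equal(heritability(vc1, 2), 0.5)

  expect_equal(genomic_correlation(vc1), diag(2))
  vc1b <- vc_model1(matrix(c(1, 0.5, 0.5, 1), 2),
                    residual_structure("IDV", 2, 1))
  expect_equal(genomic_correlation(vc1b)[1, 2], 0.5)
  set.seed(17)
  for (rep in 1:100) {
    G0 <- rand_pd(3)
    r <- genomic_correlation(vc_model1(G0, residual_structure("IDV", 3, 1)))
    expect_true(all(abs(r) <= 1 + 1e-12))
    expect_equal(diag(r), rep(1, 3))
  }
  expect_error(genomic_correlation(vc_model2(1, 1, 1)), "Model 1")
})
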