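#' Cross-validation fold plans over lines
#'
#' Partitions the lines (not records) into `k` folds for each of
#' `n_repeats` independent repeats. Fold sizes differ by at most one (the
#' first `n %% k` folds get the extra line). The same plan is meant to be
#' reused across models, structures and estimation methods so all analyses
#' see identical training/validation splits.
#'
#' @param line_ids Character vector of line identifiers.
#' @param k Number of folds (default 5, i.e. 80/20 training/validation).
#' @param n_repeats Number of independent repeats (default 10).
#' @param seed Integer seed; plans are deterministic given the seed.
#' @return An object of class `fold_plan`: a list with one element per
#'   repeat, each a list of `k` character vectors of held-out lines.
#' @export
make_folds <- function(line_ids, k = 5, n_repeats = 10, seed = 1L) {
  n <- length(line_ids)
  if (n < k) stop("fewer lines than folds")
  set.seed(seed)
  plans <- lapply(seq_len(n_repeats), function(r) {
    perm <- sample(line_ids)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    split(perm, rep(seq_len(k), times = sizes))
  })
  structure(plans, class = "fold_plan", k = k, n_repeats = n_repeats,
            seed = seed)
}

#' Training/validation record split for the M_CV scheme
#'
#' Multiple-environment cross validation: the held-out lines enter the
#' validation set with their records from every environment; training is
#' all observed records of the remaining lines. Unobserved cells appear in
#' neither set.
#'
#' @param fold_lines Character vector of held-out lines.
#' @param phenotypes Long phenotype table (`line`, `env`, `value`).
#' @return List with data frames `train` and `validation`.
#' @export
split_mcv <- function(fold_lines, phenotypes) {
  ph <- phenotypes[!is.na(phenotypes$value), , drop = FALSE]
  in_fold <- ph$line %in% fold_lines
  out <- list(train = ph[!in_fold, , drop = FALSE],
              validation = ph[in_fold, , drop = FALSE])
  if (nrow(out$train) == 0) stop("empty training set")
  out
}

#' Training/validation record split for the S_CV scheme
#'
#' Single-environment cross validation: only the held-out lines' records in
#' `target_env` are validated; their records from the other environments
#' stay in the training set (mimicking a line tested in some environments
#' but missing in the target one).
#'
#' @inheritParams split_mcv
#' @param target_env Environment label to hold out.
#' @return List with data frames `train` and `validation`.
#' @export
split_scv <- function(fold_lines, phenotypes, target_env) {
  ph <- phenotypes[!is.na(phenotypes$value), , drop = FALSE]
  if (!target_env %in% ph$env) stop("unknown target environment")
  hold <- ph$line %in% fold_lines & ph$env == target_env
  out <- list(train = ph[!hold, , drop = FALSE],
              validation = ph[hold, , drop = FALSE])
  if (nrow(out$train) == 0) stop("empty training set")
  out
}

#' Pearson prediction ability
#'
#' Sample Pearson correlation between observed phenotypes and predicted
#' GEBVs of a validation set (computed within one environment). Undefined
#' correlations (zero variance) raise an error rather than returning 0.
#'
#' @param observed,predicted Paired numeric vectors (>= 3 finite pairs).
#' @return Correlation in \[-1, 1\].
#' @export
prediction_ability <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3) stop("need at least 3 paired finite values")
  o <- observed[ok]
  p <- predicted[ok]
  if (stats::sd(o) == 0 || stats::sd(p) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(o, p)
}

#' Cross-validated genomic prediction ability
#'
#' Runs k-fold cross validation repeated `n_repeats` times for one model /
#' residual structure / estimation method, under the M_CV and/or S_CV
#' hold-out schemes, and scores per-environment Pearson prediction ability.
#' For each (repeat, fold) the variance components are estimated once on
#' the complete-line training set (the M_CV training records, with the
#' held-out lines' phenotypes removed entirely); predictions then condition
#' on the scheme's training records at those estimates, so S_CV predictions
#' for the multivariate model borrow the held-out lines' records from the
#' other environments through the genetic and residual covariances. The
#' Bayesian path refits its chain per scheme with validation cells treated
#' as missing (data augmentation). Per repeat, the five folds are pooled
#' before correlating, giving one ability value per repeat and environment;
#' the report aggregates mean and SD over repeats. Model 3 is cross
#' validated per environment independently (the "RND" rows of a MET
#' report).
#'
#' @inheritParams solve_mme
#' @param phenotypes Long phenotype table (`line`, `env`, `value`).
#' @param model 1, 2 or 3.
#' @param structure Residual structure kind (Model 1: US/IDH/IDV/ANT1;
#'   Model 2: IDV/IDH; ignored for Model 3).
#' @param method `"reml"` or `"mcmc"`.
#' @param schemes Subset of `c("mcv", "scv")` (Model 3 ignores schemes).
#' @param k,n_repeats Folds and repeats (defaults 5 and 10).
#' @param seed Seed for the fold plans and the MCMC chains.
#' @param mcmc Optional list of chain settings (`n_iter`, `burnin`, `thin`)
#'   for `method = "mcmc"`; defaults 10000/3000/10.
#' @param folds Optional [make_folds()] plan to reuse across calls.
#' @return A `cv_report` data frame with columns `env`, `model`,
#'   `structure`, `scheme`, `method`, `mean`, `sd`, `n_repeats`; per-repeat
#'   values are in `attr(, "repeats")`, failed fits are counted in
#'   `attr(, "n_failed")`.
#' @export
run_cv <- function(phenotypes, K, model = 1, structure = "US",
                   method = c("reml", "mcmc"), schemes = c("mcv", "scv"),
                   k = 5, n_repeats = 10, seed = 1L, mcmc = list(),
                   folds = NULL) {
  method <- match.arg(method)
  model <- as.integer(model)
  schemes <- match.arg(schemes, c("mcv", "scv"), several.ok = TRUE)
  mc <- utils::modifyList(list(n_iter = 10000, burnin = 3000, thin = 10),
                          mcmc)
  ph <- phenotypes[!is.na(phenotypes$value), , drop = FALSE]
  ph$line <- as.character(ph$line)
  ph$env <- as.character(ph$env)
  env_levels <- unique(ph$env)
  l <- length(env_levels)
  if (inherits(K, "kinship_eigen")) K <- K$K
  K <- as.matrix(K)
  if (is.null(rownames(K))) stop("K needs line identifiers as row names")
  line_ids <- rownames(K)
  if (!all(ph$line %in% line_ids)) stop("phenotyped lines missing from K")
  if (is.null(folds)) folds <- make_folds(line_ids, k, n_repeats, seed)
  if (model == 3L) schemes <- "rnd"

  ## per-repeat, per-env, per-scheme predicted/observed pools
  cells <- expand.grid(env = env_levels, scheme = schemes,
                       stringsAsFactors = FALSE)
  rep_vals <- matrix(NA_real_, length(folds), nrow(cells))
  n_failed <- 0L
  warm <- new.env(parent = emptyenv())   # warm-start across folds

  for (r in seq_along(folds)) {
    pred_pool <- list()
    for (f in seq_along(folds[[r]])) {
      fold_lines <- folds[[r]][[f]]
      res <- tryCatch(
        cv_fold(ph, K, line_ids, env_levels, model, structure, method,
                schemes, fold_lines, mc,
                chain_seed = seed + 1000L * r + f, warm = warm),
        error = function(e) {
          warning("fold fit failed (repeat ", r, ", fold ", f, "): ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      pred_pool[[length(pred_pool) + 1L]] <- res
    }
    if (!length(pred_pool)) next
    pooled <- do.call(rbind, pred_pool)
    for (ci in seq_len(nrow(cells))) {
      sel <- pooled$env == cells$env[ci] & pooled$scheme == cells$scheme[ci]
      if (sum(sel) >= 3) {
        rep_vals[r, ci] <- tryCatch(
          prediction_ability(pooled$observed[sel], pooled$predicted[sel]),
          error = function(e) NA_real_)
      }
    }
  }

  out <- data.frame(env = cells$env,
                    model = model,
                    structure = if (model == 3L) "-" else structure,
                    scheme = toupper(sub("mcv", "M_CV",
                                     sub("scv", "S_CV", cells$scheme))),
                    method = method,
                    mean = colMeans(rep_vals, na.rm = TRUE),
                    sd = apply(rep_vals, 2, stats::sd, na.rm = TRUE),
                    n_repeats = colSums(!is.na(rep_vals)),
                    stringsAsFactors = FALSE)
  out$scheme <- ifelse(out$scheme == "RND", "RND", out$scheme)
  class(out) <- c("cv_report", "data.frame")
  attr(out, "repeats") <- rep_vals
  attr(out, "n_failed") <- n_failed
  out
}

## fit one fold and return (line, env, scheme, observed, predicted) rows
cv_fold <- function(ph, K, line_ids, env_levels, model, structure, method,
                    schemes, fold_lines, mc, chain_seed,
                    warm = new.env(parent = emptyenv())) {
  out <- list()
  if (model == 3L) {
    ## per-environment univariate CV
    for (ev in env_levels) {
      ph_e <- ph[ph$env == ev, , drop = FALSE]
      sp <- split_mcv(fold_lines, ph_e)
      if (nrow(sp$validation) == 0) next
      train_lines <- unique(sp$train$line)
      if (method == "reml") {
        d <- build_design(sp$train, line_ids = train_lines, model = 3)
        fit <- reml_fit(d, K[train_lines, train_lines], "IDV")
        dall <- build_design(sp$train, line_ids = line_ids, model = 3)
        pred <- solve_mme(dall, fit$vc_hat, K)$gebv[, 1]
      } else {
        masked <- ph_e
        masked$value[masked$line %in% fold_lines] <- NA
        d <- build_design(masked, line_ids = line_ids, model = 3)
        chain <- run_mcmc(d, K, model = 3, structure_kind = "IDV",
                          n_iter = mc$n_iter, burnin = mc$burnin,
                          thin = mc$thin, seed = chain_seed)
        pred <- point_gebv(chain)[, 1]
      }
      idx <- match(sp$validation$line, line_ids)
      out[[length(out) + 1L]] <- data.frame(
        line = sp$validation$line, env = ev, scheme = "rnd",
        observed = sp$validation$value, predicted = pred[idx],
        stringsAsFactors = FALSE)
    }
    return(do.call(rbind, out))
  }

  sp_m <- split_mcv(fold_lines, ph)
  train_lines <- setdiff(line_ids, fold_lines)
  vc_hat <- NULL
  if (method == "reml") {
    ## variance components from the complete-line training records
    d_tr <- build_design(sp_m$train, line_ids = intersect(
      train_lines, unique(sp_m$train$line)), model = model,
      env_levels = env_levels)
    ## warm-start from the previous fold's estimate (same optimum target up
    ## to fold noise); fall back to the univariate initialization on failure
    fit_tr <- NULL
    if (!is.null(warm$vc)) {
      fit_tr <- tryCatch(reml_fit(d_tr, K, structure, init = warm$vc),
                         error = function(e) NULL)
    }
    if (is.null(fit_tr)) fit_tr <- reml_fit(d_tr, K, structure)
    vc_hat <- fit_tr$vc_hat
    warm$vc <- vc_hat
  }

  for (scheme in schemes) {
    if (scheme == "mcv") {
      sp <- sp_m
      targets <- list(NULL)
    } else {
      targets <- env_levels
    }
    for (tg in targets) {
      if (scheme == "scv") sp <- split_scv(fold_lines, ph, tg)
      if (nrow(sp$validation) == 0) next
      if (method == "reml") {
        d_pred <- build_design(sp$train, line_ids = line_ids,
                               model = model, env_levels = env_levels)
        gebv <- solve_mme(d_pred, vc_hat, K)$gebv
      } else {
        masked <- ph
        hold <- if (scheme == "mcv") masked$line %in% fold_lines
                else masked$line %in% fold_lines & masked$env == tg
        masked$value[hold] <- NA
        d_b <- build_design(masked, line_ids = line_ids, model = model,
                            env_levels = env_levels)
        chain <- run_mcmc(d_b, K, model = model,
                          structure_kind = structure,
                          n_iter = mc$n_iter, burnin = mc$burnin,
                          thin = mc$thin, seed = chain_seed)
        gebv <- point_gebv(chain)
      }
      idx <- cbind(match(sp$validation$line, line_ids),
                   match(sp$validation$env, env_levels))
      out[[length(out) + 1L]] <- data.frame(
        line = sp$validation$line, env = sp$validation$env,
        scheme = scheme, observed = sp$validation$value,
        predicted = gebv[idx], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Format a cross-validation report as a publication-style table
#'
#' Rows are scheme x model x structure, columns are environments, cells are
#' `"mean (sd)"` of prediction ability over repeats -- the layout used for
#' MET prediction-ability tables.
#'
#' @param ... One or more `cv_report` objects (rbind-compatible).
#' @param digits Decimal places (default 2).
#' @return A data frame of formatted cells.
#' @export
format_cv_table <- function(..., digits = 2) {
  rep_list <- list(...)
  rep_all <- do.call(rbind, lapply(rep_list, as.data.frame))
  rep_all$rowlab <- sprintf("%s (Model %d)%s", rep_all$scheme,
                            rep_all$model,
                            ifelse(rep_all$structure == "-", "",
                                   paste0(" ", rep_all$structure)))
  envs <- unique(rep_all$env)
  rows <- unique(rep_all$rowlab)
  tab <- data.frame(row.names = rows)
  for (ev in envs) {
    tab[[ev]] <- vapply(rows, function(rl) {
      z <- rep_all[rep_all$rowlab == rl & rep_all$env == ev, ]
      if (nrow(z) == 0) return("-.-")
      sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
              z$mean[1], z$sd[1])
    }, character(1))
  }
  tab
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validated prediction ability (mean over repeats, SD):\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
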