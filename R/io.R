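#' Read a long-format phenotype table
#'
#' Expects a CSV with header `line,env,value`; an empty `value` field marks
#' a missing cell. Environment labels are kept verbatim. Duplicate
#' (line, env) records and malformed rows are rejected with their line
#' numbers.
#'
#' @param path CSV file path.
#' @return Data frame with character `line`/`env` and numeric `value`
#'   (`NA` = missing) plus a logical `observed` column.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "character"))
  if (!all(c("line", "env", "value") %in% names(ph)))
    stop("phenotype file must have columns line,env,value")
  val <- suppressWarnings(as.numeric(ph$value))
  bad <- which(!is.na(ph$value) & ph$value != "" & is.na(val))
  if (length(bad))
    stop("malformed numeric value on data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  dup <- which(duplicated(ph[c("line", "env")]))
  if (length(dup))
    stop("duplicate (line, env) record on data row(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  data.frame(line = ph$line, env = ph$env, value = val,
             observed = !is.na(val), stringsAsFactors = FALSE)
}

#' Write a long-format phenotype table
#'
#' @param phenotypes Data frame with `line`, `env`, `value`.
#' @param path Output CSV path; missing values are written as empty fields.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes[c("line", "env", "value")], path,
                   row.names = FALSE, na = "", quote = FALSE)
}

#' Read / write genotype dosage matrices as CSV
#'
#' The CSV layout is lines in rows and markers in columns, with a header of
#' marker identifiers and the first column holding line identifiers.
#'
#' @param path CSV file path.
#' @return For `read_genotypes_csv`, a [marker_matrix()].
#' @export
read_genotypes_csv <- function(path) {
  g <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  marker_matrix(as.matrix(g))
}

#' @rdname read_genotypes_csv
#' @param geno Dosage matrix with dimnames.
#' @export
write_genotypes_csv <- function(geno, path) {
  utils::write.csv(as.data.frame(geno), path, row.names = TRUE,
                   quote = FALSE)
}

#' Read genotypes from a VCF file
#'
#' Extracts biallelic sites and codes the dosage as the count of the
#' alternate allele (0/1/2, `NA` for missing). Requires the `vcfR` package.
#'
#' @param path VCF (optionally gzipped) file path.
#' @return A [marker_matrix()] (lines = VCF samples).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the `vcfR` package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, 2, count_alt)
  marker_matrix(t(dos), line_ids = colnames(gt), marker_ids = rownames(gt))
}

#' Write genotypes as a minimal VCF
#'
#' Dosages are encoded as unphased diploid genotypes (0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1, `NA` -> ./.) at dummy positions on one contig.
#'
#' @param geno Dosage matrix (lines x markers).
#' @param path Output path (plain text).
#' @export
write_genotypes_vcf <- function(geno, path) {
  geno <- as.matrix(geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(geno)),
                     collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(geno))) {
    gt <- ifelse(is.na(geno[, j]), "./.", gt_code[as.character(geno[, j])])
    writeLines(paste(c("1", j, colnames(geno)[j], "A", "G", ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write a kinship matrix as CSV
#'
#' Square CSV with line identifiers as both header row and first column.
#'
#' @param K Symmetric kinship matrix with line ids as dimnames.
#' @param path CSV file path.
#' @export
write_kinship_csv <- function(K, path) {
  utils::write.csv(as.data.frame(K), path, row.names = TRUE, quote = FALSE)
}

#' @rdname write_kinship_csv
#' @export
read_kinship_csv <- function(path) {
  K <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  colnames(K) <- rownames(K)
  K
}

#' Serialize a fitted model to JSON
#'
#' Writes the fixed effects, variance components and restricted
#' log-likelihood of a [solve_mme()] / [reml_fit()] result; GEBVs go to a
#' separate CSV with one row per line and one column per environment.
#'
#' @param fit A `met_fit` or `reml_result`.
#' @param path Output JSON path.
#' @param gebv_path Optional CSV path for the GEBV matrix.
#' @export
write_fit_json <- function(fit, path, gebv_path = NULL) {
  if (inherits(fit, "reml_result")) {
    meta <- list(converged = fit$converged, n_iter = fit$n_iter,
                 structure = fit$structure_kind)
    fit <- fit$fit
  } else meta <- NULL
  vc <- fit$vc
  vc_out <- if (vc$model == 1L) {
    list(model = 1, G0 = vc$G0,
         R0 = structure_to_config(vc$R0))
  } else if (vc$model == 2L) {
    list(model = 2, sigma_g2 = vc$sigma_g2, sigma_v2 = vc$sigma_v2,
         sigma_e2 = vc$sigma_e2)
  } else {
    list(model = 3, sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2)
  }
  out <- list(beta_hat = as.list(stats::setNames(as.numeric(fit$beta_hat),
                                                 names(fit$beta_hat))),
              env_means = fit$env_means, variance_components = vc_out,
              loglik = fit$loglik, estimation = meta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(gebv_path))
    utils::write.csv(as.data.frame(fit$gebv), gebv_path, row.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration and fills defaults: five folds, ten repeats,
#' MCMC 10000 iterations with burn-in 3000 and thinning 10, REML
#' estimation, models 1-3, all four residual structures, both CV schemes.
#' An empty file yields the full default configuration. Unknown models,
#' structures, methods or schemes are rejected naming the offending field.
#'
#' @param path YAML file path (optional; `NULL` gives pure defaults).
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- list(
    geno = NULL, pheno = NULL, out = ".",
    models = c(1, 2, 3),
    structures = c("US", "IDH", "IDV", "ANT1"),
    method = "reml",
    schemes = c("mcv", "scv"),
    cv = list(k = 5, repeats = 10),
    mcmc = list(iters = 10000, burnin = 3000, thin = 10),
    maf_min = 0.05, max_missing = 0.20,
    seed = 1)
  cfg <- utils::modifyList(defaults, cfg)
  if (!all(cfg$models %in% 1:3))
    stop("config field `models`: must be a subset of 1, 2, 3")
  bad <- setdiff(cfg$structures, c("US", "IDH", "IDV", "ANT1"))
  if (length(bad))
    stop("config field `structures`: unknown residual kind ",
         paste(bad, collapse = ", "))
  if (!all(cfg$method %in% c("reml", "mcmc", "both")))
    stop("config field `method`: must be reml, mcmc or both")
  bad <- setdiff(cfg$schemes, c("mcv", "scv"))
  if (length(bad))
    stop("config field `schemes`: unknown scheme ",
         paste(bad, collapse = ", "))
  if (cfg$mcmc$iters <= cfg$mcmc$burnin)
    stop("config field `mcmc`: iters must exceed burnin")
  if (cfg$seed != round(cfg$seed)) stop("config field `seed`: integer")
  for (f in c("geno", "pheno")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config field `", f, "`: file not found: ", cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}
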