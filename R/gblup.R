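#' Validate a phenotype table
#'
#' A phenotype table is a long-format data frame of trial records with
#' columns `accession_id`, `env_id`, `rep`, `trait`, `value`. Keys
#' (accession, environment, replicate, trait) must be unique and values
#' finite; records with missing values are dropped.
#'
#' @param pt data frame
#' @return the validated table (missing-value records removed)
#' @export
as_phenotype_table <- function(pt) {
  need <- c("accession_id", "env_id", "rep", "trait", "value")
  if (!all(need %in% names(pt)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  pt <- pt[!is.na(pt$value), , drop = FALSE]
  if (nrow(pt) == 0) stop("phenotype table has no usable records")
  if (any(!is.finite(pt$value))) stop("phenotype values must be finite")
  key <- paste(pt$accession_id, pt$env_id, pt$rep, pt$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (accession, env, rep, trait) record(s) in phenotype table")
  pt
}

#' Read / write phenotype CSV
#'
#' Column layout: `accession_id,env_id,rep,trait,value`.
#' @param path file path
#' @export
read_phenotypes_csv <- function(path) {
  as_phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_phenotypes_csv
#' @param pt phenotype table
#' @export
write_phenotypes_csv <- function(pt, path) {
  utils::write.csv(pt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scale phenotypes to mean zero, variance one per environment
#'
#' Within each (environment, trait) group the values are centered and
#' scaled to unit sample variance (n - 1 denominator). The rule exists for
#' jointly modelling environments whose raw observations sit on different
#' ranges under a single residual variance; it therefore applies only when
#' a trait is observed in more than one environment — a single-environment
#' trait is returned unchanged.
#'
#' @param pt phenotype table
#' @return the table with scaled `value`s
#' @export
scale_phenotypes <- function(pt) {
  pt <- as_phenotype_table(pt)
  for (tr in unique(pt$trait)) {
    rows_t <- pt$trait == tr
    envs <- unique(pt$env_id[rows_t])
    if (length(envs) < 2) next
    for (env in envs) {
      rows <- rows_t & pt$env_id == env
      v <- pt$value[rows]
      if (length(v) < 2 || stats::sd(v) == 0)
        stop("cannot scale: environment ", env, " has degenerate values for ", tr)
      pt$value[rows] <- (v - mean(v)) / stats::sd(v)
    }
  }
  pt
}

#' Build a GBLUP model design
#'
#' Assembles the response `y`, the fixed-effect design `X` (one intercept
#' column per environment block; a single all-ones column when one
#' environment is modelled), and the record-to-accession incidence for the
#' mixed model `y = X b + Z u + e`, `u ~ N(0, G sigma_u^2)`. The GRM
#' defines the accession universe: every accession in `grm` gets a
#' predicted genotypic value, whether phenotyped ("tested") or not.
#'
#' @param pt phenotype table
#' @param grm GRM over all accessions to predict (tested and untested)
#' @param trait trait label to model
#' @param envs environments to include (default: all present for the trait)
#' @param scale scale phenotypes per environment first? Default: yes when
#'   more than one environment is modelled (see [scale_phenotypes()]).
#' @return a `model_design` list: `y`, `X`, `z_idx` (accession index per
#'   record), `grm`, `accession_ids`, `tested_ids`, `env`
#' @export
model_design <- function(pt, grm, trait, envs = NULL, scale = NULL) {
  pt <- as_phenotype_table(pt)
  pt <- pt[pt$trait == trait, , drop = FALSE]
  if (nrow(pt) == 0) stop("no records for trait ", trait)
  if (!is.null(envs)) pt <- pt[pt$env_id %in% envs, , drop = FALSE]
  if (nrow(pt) == 0) stop("no records for the requested environments")
  env <- factor(pt$env_id)
  if (is.null(scale)) scale <- nlevels(env) > 1
  if (scale && nlevels(env) > 1) pt <- scale_phenotypes(pt)

  ids <- rownames(grm)
  unknown <- setdiff(pt$accession_id, ids)
  if (length(unknown) > 0)
    stop("phenotyped accession(s) absent from GRM: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  X <- if (nlevels(env) == 1) matrix(1, nrow(pt), 1,
                                     dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(~ 0 + env)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is singular")
  structure(
    list(y = pt$value, X = X,
         z_idx = match(pt$accession_id, ids),
         grm = grm, accession_ids = ids,
         tested_ids = unique(pt$accession_id),
         env = as.character(env)),
    class = "model_design"
  )
}

# EMMA-style REML for a single variance component.
#
# y = X b + e*, Var(e*) = sigma_u^2 K + sigma_e^2 I, K = Z G Z'.
# Eigendecompose S (K + I) S with S the projection off the column space of
# X; the top n-p eigenvalues minus one give the spectrum of K restricted to
# the error contrasts, and the restricted log-likelihood becomes a cheap
# 1-D function of the ratio delta = sigma_e^2 / sigma_u^2. A coarse
# log-scale grid brackets the optimum before stats::optimize refines it.
reml_emma <- function(y, X, K, ratio_bounds = c(1e-6, 1e6), tol = 1e-8) {
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("not enough records to estimate variance components")
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
  xi <- pmax(es$values[seq_len(n - p)] - 1, 0)
  eta <- drop(crossprod(es$vectors[, seq_len(n - p), drop = FALSE], y))
  eta2 <- eta^2
  # normalized spectrum makes the objective exactly scale-invariant in y,
  # so rescaling the response cannot perturb the ratio estimate
  eta2n <- eta2 / sum(eta2)

  rll <- function(log_delta) {
    dxi <- xi + exp(log_delta)
    0.5 * ((n - p) * (log((n - p) / (2 * pi)) - 1 - log(sum(eta2n / dxi)) -
                        log(sum(eta2))) - sum(log(dxi)))
  }
  # derivative of rll in log_delta, for polishing the interior optimum to
  # stationarity (the likelihood is flat near the maximum, so a value-based
  # search alone leaves O(sqrt(eps)) noise in the ratio)
  score <- function(log_delta) {
    d <- exp(log_delta); dxi <- xi + d
    0.5 * d * ((n - p) * sum(eta2n / dxi^2) / sum(eta2n / dxi) - sum(1 / dxi))
  }
  grid <- seq(log(ratio_bounds[1]), log(ratio_bounds[2]), length.out = 100)
  vals <- vapply(grid, rll, 0)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE, tol = tol)
  l_hat <- opt$maximum
  if (score(lo) > 0 && score(hi) < 0)
    l_hat <- stats::uniroot(score, c(lo, hi), tol = 1e-14)$root
  delta <- exp(l_hat)
  sigma_u2 <- sum(eta2 / (xi + delta)) / (n - p)
  list(sigma_u2 = sigma_u2, sigma_e2 = delta * sigma_u2,
       delta = delta, reml_loglik = rll(l_hat))
}

#' Fit the GBLUP mixed model by REML
#'
#' Estimates the genotypic and residual variances of
#' `y = X b + Z u + e`, `u ~ N(0, G sigma_u^2)`, `e ~ N(0, I sigma_e^2)`
#' by maximizing the restricted likelihood over the variance ratio
#' (spectral EMMA-style solver: one symmetric eigendecomposition, then a
#' derivative-free 1-D search on the log ratio in `[1e-6, 1e6]`). Fixed
#' effects come from generalized least squares at the optimum, and the
#' genotypic values of every accession in the GRM — tested or not — are
#' the BLUP conditional means
#' `u_hat = sigma_u^2 G Z' V^{-1} (y - X b_hat)`.
#'
#' @param design a [model_design()]
#' @param ratio_bounds search range for `sigma_e^2 / sigma_u^2`
#' @param tol optimizer tolerance on the log ratio
#' @return a `gblup_fit`: `beta`, `sigma2_u`, `sigma2_e`, `h2`
#'   (`sigma2_u / (sigma2_u + sigma2_e)`), `u_hat` (named, all GRM
#'   accessions), `reml_loglik`, `tested_ids`, plus the design
#' @export
fit_gblup_reml <- function(design, ratio_bounds = c(1e-6, 1e6), tol = 1e-10) {
  stopifnot(inherits(design, "model_design"))
  y <- design$y; X <- design$X
  G <- unclass(design$grm); idx <- design$z_idx
  K <- G[idx, idx, drop = FALSE]
  est <- reml_emma(y, X, K, ratio_bounds, tol)

  V <- est$sigma_u2 * K + diag(est$sigma_e2, length(y))
  Vinv_y <- solve(V, y)
  Vinv_X <- solve(V, X)
  beta <- drop(solve(crossprod(X, Vinv_X), crossprod(X, Vinv_y)))
  names(beta) <- colnames(X)
  r <- y - drop(X %*% beta)
  u_hat <- drop(est$sigma_u2 * G[, idx, drop = FALSE] %*% solve(V, r))
  names(u_hat) <- design$accession_ids

  structure(
    list(beta = beta, sigma2_u = est$sigma_u2, sigma2_e = est$sigma_e2,
         h2 = est$sigma_u2 / (est$sigma_u2 + est$sigma_e2),
         u_hat = u_hat, reml_loglik = est$reml_loglik,
         tested_ids = design$tested_ids, design = design),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "<gblup_fit> %d records, %d accessions (%d tested)\n  sigma2_u = %.4g, sigma2_e = %.4g (h2 = %.3f), REML logLik = %.4f\n",
    length(x$design$y), length(x$u_hat), length(x$tested_ids),
    x$sigma2_u, x$sigma2_e, x$h2, x$reml_loglik
  ))
  invisible(x)
}

#' Fit GBLUP straight from a phenotype table
#'
#' Convenience wrapper: [model_design()] then [fit_gblup_reml()].
#' @inheritParams model_design
#' @param ... passed to [fit_gblup_reml()]
#' @export
fit_gblup <- function(pt, grm, trait, envs = NULL, scale = NULL, ...) {
  fit_gblup_reml(model_design(pt, grm, trait, envs, scale), ...)
}

#' Extract predicted genotypic values
#'
#' `"tested"` are accessions with at least one phenotype record in the
#' fit; `"untested"` accessions carry predicted genotypic values (PGVs)
#' through their genomic relationships alone.
#'
#' @param fit a `gblup_fit`
#' @param subset `"all"`, `"tested"` or `"untested"`
#' @return named numeric vector of genotypic values
#' @export
predict_genotypic_values <- function(fit, subset = c("all", "tested", "untested")) {
  subset <- match.arg(subset)
  u <- fit$u_hat
  switch(subset,
         all = u,
         tested = u[names(u) %in% fit$tested_ids],
         untested = u[!names(u) %in% fit$tested_ids])
}

#' Estimate broad-sense heritability from a replicated trial
#'
#' Fits `y_ij = g_i + r_j + e_ij` within one environment, with genotype
#' effects `g_i` random under an identity covariance (no genomic
#' information) and replicate effects fixed, by the same REML engine as
#' the GBLUP fit. Returns `H2 = V_g / (V_g + V_e / R)` where `R` is the
#' number of replicates.
#'
#' @param pt phenotype table
#' @param env environment id
#' @param trait trait label
#' @return a `heritability_estimate` list: `V_g`, `V_e`, `R`, `H2`
#' @export
estimate_heritability <- function(pt, env, trait) {
  pt <- as_phenotype_table(pt)
  pt <- pt[pt$env_id == env & pt$trait == trait, , drop = FALSE]
  if (nrow(pt) == 0) stop("no records for trait ", trait, " in ", env)
  R <- length(unique(pt$rep))
  if (R < 2)
    stop("insufficient replication: broad-sense heritability needs >= 2 replicates")
  X <- stats::model.matrix(~ factor(rep), data = pt)
  acc <- factor(pt$accession_id)
  Z <- stats::model.matrix(~ 0 + acc)
  est <- reml_emma(pt$value, X, tcrossprod(Z))
  H2 <- est$sigma_u2 / (est$sigma_u2 + est$sigma_e2 / R)
  structure(list(V_g = est$sigma_u2, V_e = est$sigma_e2, R = R, H2 = H2),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("<heritability> V_g = %.4g, V_e = %.4g, R = %d, H2 = %.3f\n",
              x$V_g, x$V_e, x$R, x$H2))
  invisible(x)
}
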