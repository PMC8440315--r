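# Shared fixtures: everything is generated in code at test time.

# One-environment simulated study, small by default.
quick_sim <- function(n_pool = 200, n_train = 120, n_markers = 400,
                      h2 = 0.5, n_reps = 1, genetic_corr = 0.6,
                      envs = "E1", intercepts = NULL, missing_rate = 0,
                      n_qtl = n_markers, seed = 1) {
  if (is.null(intercepts)) intercepts <- stats::setNames(rep(0, length(envs)), envs)
  h2v <- stats::setNames(rep_len(h2, length(envs)), envs)
  cfg <- sim_config(n_pool = n_pool, n_train = n_train, n_markers = n_markers,
                    n_qtl = n_qtl, h2_per_env = h2v, env_intercepts = intercepts,
                    genetic_corr = genetic_corr, n_reps = n_reps,
                    missing_rate = missing_rate, seed = seed)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  list(cfg = cfg, g = g, pt = sim$phenotypes, truth = sim$truth,
       grm = compute_grm(impute_mean(g)))
}

# Tiny labelled genotype matrix from a plain matrix of dosages.
toy_genotypes <- function(d) {
  dimnames(d) <- list(sprintf("A%02d", seq_len(nrow(d))),
                      sprintf("M%02d", seq_len(ncol(d))))
  genotype_matrix(d)
}

# Identity GRM with accession ids.
identity_grm <- function(n, ids = sprintf("A%02d", seq_len(n))) {
  structure(diag(n), dimnames = list(ids, ids), class = c("grm", "matrix"))
}

# Well-conditioned random GRM (no ridge triggered downstream).
random_grm <- function(n, m = 4 * n, jitter = 0.5) {
  W <- matrix(stats::rnorm(n * m), n)
  G <- tcrossprod(W) / m + diag(jitter, n)
  ids <- sprintf("A%02d", seq_len(n))
  structure((G + t(G)) / 2, dimnames = list(ids, ids),
            class = c("grm", "matrix"))
}

# Independent dense restricted-likelihood profile over the heritability
# ratio h = sigma_u^2 / (sigma_u^2 + sigma_e^2), used as the REML oracle.
# Direct formula: -2 rll = (n-p) log s2 + log|V0| + log|X' V0^-1 X| + (n-p),
# V0 = h K + (1-h) I, s2 profiled out.
reml_profile_oracle <- function(y, X, K) {
  n <- length(y); p <- ncol(X)
  function(h) {
    V0 <- h * K + (1 - h) * diag(n)
    cV <- chol(V0)
    Vi <- chol2inv(cV)
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
    s2 <- drop(crossprod(y, P %*% y)) / (n - p)
    -0.5 * ((n - p) * log(s2) + 2 * sum(log(diag(cV))) +
              as.numeric(determinant(XtViX)$modulus) + (n - p))
  }
}

# Long-format phenotype records from parallel vectors.
make_pt <- function(accession_id, value, env_id = "E1", rep = 1,
                    trait = "TR") {
  data.frame(accession_id = accession_id, env_id = env_id, rep = rep,
             trait = trait, value = value, stringsAsFactors = FALSE)
}
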