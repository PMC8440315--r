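#' Simulation configuration
#'
#' Describes a synthetic gene-bank study: a pool of accessions genotyped at
#' independent biallelic SNPs, of which a training subset is phenotyped in
#' one or more site-year environments with a shared additive architecture.
#' Defaults emulate a multi-environment low-input field study on a large
#' rice gene-bank panel: a pool of 3,000 accessions, ~400 phenotyped in two
#' sites with two replicates, per-environment broad-sense heritabilities in
#' the range reported for biomass traits, and a moderate cross-site genetic
#' correlation. All architecture choices (Gaussian effects at `n_qtl`
#' random markers, independent markers, equicorrelated cross-environment
#' effects) are stand-ins: the emulated study does not describe its trait
#' architecture.
#'
#' @param n_pool accessions in the full pool
#' @param n_train phenotyped (training) accessions, drawn at random from
#'   the pool
#' @param n_markers biallelic SNP count
#' @param maf_range range of minor allele frequencies, within (0, 0.5]
#' @param n_qtl markers with nonzero effect
#' @param h2_per_env named vector, environment id -> heritability in (0,1),
#'   enforced at the accession-mean (across replicates) level
#' @param env_intercepts named vector, environment id -> trait mean on the
#'   raw scale; must share names with `h2_per_env`
#' @param genetic_corr cross-environment genetic correlation (equicorrelation
#'   across environments; must keep the correlation matrix PSD)
#' @param n_reps replicates per environment (>= 1)
#' @param missing_rate genotype missingness fraction in [0, 1)
#' @param trait trait label used in the phenotype table
#' @param seed integer RNG seed (< 2^31 - 1)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_pool = 3000, n_train = 400, n_markers = 2000,
                       maf_range = c(0.025, 0.5), n_qtl = 300,
                       h2_per_env = c(Anjiro = 0.62, Behenjy = 0.73),
                       env_intercepts = c(Anjiro = 55, Behenjy = 35),
                       genetic_corr = 0.6, n_reps = 2, missing_rate = 0.02,
                       trait = "STW", seed = 1) {
  cfg <- list(n_pool = as.integer(n_pool), n_train = as.integer(n_train),
              n_markers = as.integer(n_markers), maf_range = maf_range,
              n_qtl = as.integer(n_qtl), h2_per_env = h2_per_env,
              env_intercepts = env_intercepts, genetic_corr = genetic_corr,
              n_reps = as.integer(n_reps), missing_rate = missing_rate,
              trait = trait, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_pool < 1 || n_markers < 1 || n_train < 1 || n_qtl < 1 || n_reps < 1)
      stop("sim_config: counts must be positive")
    if (n_train > n_pool) stop("sim_config: n_train must be <= n_pool")
    if (n_qtl > n_markers) stop("sim_config: n_qtl must be <= n_markers")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("sim_config: maf_range must be within (0, 0.5] and increasing")
    if (is.null(names(h2_per_env)) || any(names(h2_per_env) == ""))
      stop("sim_config: h2_per_env must be a named vector of environments")
    if (any(h2_per_env <= 0 | h2_per_env >= 1))
      stop("sim_config: every h2 must lie in (0, 1)")
    if (!setequal(names(env_intercepts), names(h2_per_env)))
      stop("sim_config: env_intercepts and h2_per_env must name the same environments")
    n_env <- length(h2_per_env)
    if (genetic_corr > 1 || (n_env > 1 && genetic_corr < -1 / (n_env - 1)))
      stop("sim_config: genetic_corr outside the PSD range for ", n_env,
           " environments")
    if (missing_rate < 0 || missing_rate >= 1)
      stop("sim_config: missing_rate must be in [0, 1)")
    if (abs(seed) >= 2^31 - 2) stop("sim_config: seed too large")
  })
  invisible(cfg)
}

#' Simulate a genotype pool
#'
#' Draws each marker's alternate allele frequency uniformly from
#' `maf_range`, then samples diploid dosages under Hardy-Weinberg
#' proportions, `dosage ~ Binomial(2, p)`, independently across markers
#' (no linkage disequilibrium). Missing calls are inserted uniformly at
#' `missing_rate`. Deterministic for a fixed config.
#'
#' @param config a [sim_config()]
#' @return a [genotype_matrix()] of dimension `n_pool` x `n_markers`
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_pool; m <- config$n_markers
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  d <- vapply(p, function(pj) stats::rbinom(n, 2L, pj), numeric(n))
  if (config$missing_rate > 0)
    d[stats::runif(length(d)) < config$missing_rate] <- NA_real_
  dimnames(d) <- list(sprintf("ACC%05d", seq_len(n)),
                      sprintf("SNP%06d", seq_len(m)))
  genotype_matrix(d)
}

#' Simulate multi-environment replicated phenotypes with known truth
#'
#' Picks `n_qtl` markers, draws their additive effects for every
#' environment from an equicorrelated multivariate Gaussian with
#' correlation `genetic_corr`, and forms per-environment true genotypic
#' values `u = W_c b` from mean-imputed, column-centered dosages, centered
#' to mean zero over the pool. A random training subset of `n_train`
#' accessions receives `n_reps` phenotype records per environment:
#' `value = intercept_env + u + e`. The single-record residual SD is set
#' from the empirical variance of `u` over the training set so that
#' `Var(u) / (Var(u) + sigma_e^2 / n_reps)` — heritability at the
#' accession-mean level — equals the configured `h2_per_env`.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()]
#' @param config the same [sim_config()]
#' @return a list with `phenotypes` (long-format data frame:
#'   `accession_id`, `env_id`, `rep`, `trait`, `value`) and `truth`
#'   (a `sim_truth` list: `marker_effects` matrix (marker x environment,
#'   zeros off-QTL), `true_genotypic_values` (pool x environment),
#'   `realized_h2`, `sigma_e` (single-record residual SD per environment),
#'   `train_ids`, `qtl_idx`)
#' @export
simulate_phenotypes <- function(genotypes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  envs <- names(config$h2_per_env)
  n_env <- length(envs)
  d <- impute_mean(genotypes)$dosages
  Wc <- sweep(d, 2, colMeans(d))

  qtl <- sort(sample.int(ncol(d), config$n_qtl))
  R <- matrix(config$genetic_corr, n_env, n_env); diag(R) <- 1
  # symmetric square root tolerates the singular genetic_corr = 1 limit
  er <- eigen(R, symmetric = TRUE)
  sqrtR <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  B <- matrix(stats::rnorm(config$n_qtl * n_env), config$n_qtl) %*% sqrtR
  effects <- matrix(0, ncol(d), n_env,
                    dimnames = list(colnames(d), envs))
  effects[qtl, ] <- B

  U <- Wc[, qtl, drop = FALSE] %*% B
  U <- sweep(U, 2, colMeans(U))
  dimnames(U) <- list(rownames(d), envs)

  train <- sort(sample.int(nrow(d), config$n_train))
  train_ids <- rownames(d)[train]

  sigma_e <- realized <- stats::setNames(numeric(n_env), envs)
  recs <- vector("list", n_env)
  for (k in seq_len(n_env)) {
    env <- envs[k]
    h2 <- config$h2_per_env[[env]]
    v_u <- stats::var(U[train, k])
    sigma_e[env] <- sqrt(config$n_reps * v_u * (1 - h2) / h2)
    realized[env] <- v_u / (v_u + sigma_e[env]^2 / config$n_reps)
    e <- stats::rnorm(config$n_train * config$n_reps, 0, sigma_e[env])
    recs[[k]] <- data.frame(
      accession_id = rep(train_ids, times = config$n_reps),
      env_id = env,
      rep = rep(seq_len(config$n_reps), each = config$n_train),
      trait = config$trait,
      value = config$env_intercepts[[env]] + rep(U[train, k], config$n_reps) + e,
      stringsAsFactors = FALSE
    )
  }
  pt <- do.call(rbind, recs)
  rownames(pt) <- NULL
  truth <- structure(
    list(marker_effects = effects, true_genotypic_values = U,
         realized_h2 = realized, sigma_e = sigma_e,
         env_intercepts = config$env_intercepts[envs],
         train_ids = train_ids, qtl_idx = qtl),
    class = "sim_truth"
  )
  list(phenotypes = pt, truth = truth)
}

#' Phenotype additional accessions under an existing simulated truth
#'
#' Generates `n_reps` records per environment for the given accessions
#' using the marker effects, intercepts and residual SDs frozen in a
#' [simulate_phenotypes()] truth object — the mechanism behind multi-cycle
#' selection demos, where newly selected accessions are "grown out" and
#' added to the training set.
#'
#' @param truth a `sim_truth`
#' @param accessions character vector of pool accession ids
#' @param n_reps replicates per environment
#' @param trait trait label
#' @param seed RNG seed for the new residuals
#' @return long-format phenotype data frame
#' @export
phenotype_accessions <- function(truth, accessions, n_reps = 2,
                                 trait = "STW", seed = 1) {
  U <- truth$true_genotypic_values
  missing <- setdiff(accessions, rownames(U))
  if (length(missing) > 0)
    stop("unknown accession id(s): ", paste(utils::head(missing, 5), collapse = ", "))
  set.seed(seed)
  envs <- colnames(U)
  recs <- lapply(envs, function(env) {
    u <- U[accessions, env]
    data.frame(
      accession_id = rep(accessions, times = n_reps),
      env_id = env,
      rep = rep(seq_len(n_reps), each = length(accessions)),
      trait = trait,
      value = truth$env_intercepts[[env]] + rep(u, n_reps) +
        stats::rnorm(length(accessions) * n_reps, 0, truth$sigma_e[[env]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write simulated truth as TSV
#'
#' @param truth a `sim_truth`
#' @param path output path; one row per accession with the true genotypic
#'   value in each environment
#' @export
write_truth_tsv <- function(truth, path) {
  U <- truth$true_genotypic_values
  df <- data.frame(accession_id = rownames(U), U, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
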