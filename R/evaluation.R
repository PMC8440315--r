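# Accession-mean observed values for one (env, trait): replicate means
# unify unreplicated and replicated trials for accuracy computation.
accession_means <- function(pt, trait, env) {
  pt <- pt[pt$trait == trait & pt$env_id == env, , drop = FALSE]
  if (nrow(pt) == 0) return(stats::setNames(numeric(0), character(0)))
  tapply(pt$value, pt$accession_id, mean)
}

#' Repeated k-fold cross-validation of prediction accuracy
#'
#' Accessions (never individual records, so replicates cannot leak) are
#' partitioned into `k` random folds; each fold's accessions are held out,
#' the GBLUP model is refitted on the remaining records, and held-out
#' accessions receive PGVs. Accuracy is the Pearson correlation between
#' PGVs and observed accession means within the environment. By default
#' predictions are pooled over the k folds and one correlation is computed
#' per repeat ("pooled"); `aggregate = "per_fold"` averages fold-level
#' correlations instead. Reported are the mean and SD over repeats.
#'
#' @param pt phenotype table
#' @param grm GRM covering the phenotyped accessions
#' @param trait trait label
#' @param env environment id (the protocol runs within one environment)
#' @param k folds (default 10)
#' @param repeats repetitions of the whole k-fold split (default 10)
#' @param seed RNG seed
#' @param aggregate `"pooled"` or `"per_fold"`
#' @return a `cv_result` list: `trait`, `env`, `mean_accuracy`,
#'   `sd_accuracy`, `accuracies` (per repeat), `n_folds`, `n_repeats`,
#'   `n_accessions`, `seed`
#' @export
kfold_cv <- function(pt, grm, trait, env, k = 10, repeats = 10, seed = 1,
                     aggregate = c("pooled", "per_fold")) {
  aggregate <- match.arg(aggregate)
  pt <- as_phenotype_table(pt)
  pt <- pt[pt$trait == trait & pt$env_id == env, , drop = FALSE]
  if (nrow(pt) == 0) stop("no records for trait ", trait, " in ", env)
  obs <- accession_means(pt, trait, env)
  acc <- names(obs)
  if (length(acc) < 2 * k)
    stop("need at least 2k phenotyped accessions for ", k, "-fold CV")
  set.seed(seed)
  rep_acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), length(acc)))
    if (min(tabulate(fold, k)) < 3)
      stop("fold with fewer than 3 test accessions; reduce k")
    pred <- stats::setNames(numeric(length(acc)), acc)
    fold_r <- numeric(k)
    for (f in seq_len(k)) {
      test <- acc[fold == f]
      train_pt <- pt[!pt$accession_id %in% test, , drop = FALSE]
      fit <- fit_gblup(train_pt, grm, trait)
      pred[test] <- fit$u_hat[test]
      fold_r[f] <- stats::cor(pred[test], obs[test])
    }
    rep_acc[r] <- if (aggregate == "pooled") stats::cor(pred, obs)
    else mean(fold_r)
  }
  structure(
    list(trait = trait, env = env,
         mean_accuracy = mean(rep_acc), sd_accuracy = stats::sd(rep_acc),
         accuracies = rep_acc, n_folds = k, n_repeats = repeats,
         n_accessions = length(acc), seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s @ %s: accuracy %.3f (SD %.3f) over %d x %d-fold CV, n = %d\n",
              x$trait, x$env, x$mean_accuracy, x$sd_accuracy,
              x$n_repeats, x$n_folds, x$n_accessions))
  invisible(x)
}

#' Forward validation: train on one season, test on the next
#'
#' Fits GBLUP on the training table only and correlates the resulting
#' PGVs with the test table's observed accession means, separately for
#' accessions phenotyped in both seasons (`repeated_set`) and accessions
#' new in the test season (`new_set`, which must be disjoint from the
#' training accessions).
#'
#' @param train_pt,test_pt phenotype tables for the two seasons
#' @param grm GRM covering all involved accessions
#' @param trait trait label
#' @param repeated_set accessions present in both seasons (subset of the
#'   training accessions)
#' @param new_set accessions only in the test season
#' @param test_env environment id within `test_pt` to evaluate against
#'   (default: all test records pooled by accession mean)
#' @param ... passed to [fit_gblup()] (e.g. `envs`, `scale`)
#' @return a `forward_validation_result`: per-subset accuracy and counts
#' @export
forward_validation <- function(train_pt, test_pt, grm, trait,
                               repeated_set, new_set, test_env = NULL, ...) {
  train_pt <- as_phenotype_table(train_pt)
  test_pt <- as_phenotype_table(test_pt)
  train_acc <- unique(train_pt$accession_id[train_pt$trait == trait])
  if (length(intersect(new_set, train_acc)) > 0)
    stop("`new_set` must be disjoint from the training accessions")
  if (!all(repeated_set %in% train_acc))
    stop("`repeated_set` must be a subset of the training accessions")
  fit <- fit_gblup(train_pt, grm, trait, ...)
  tpt <- test_pt[test_pt$trait == trait, , drop = FALSE]
  if (!is.null(test_env)) tpt <- tpt[tpt$env_id %in% test_env, , drop = FALSE]
  obs <- tapply(tpt$value, tpt$accession_id, mean)
  one <- function(set, label) {
    set <- intersect(set, names(obs))
    if (length(set) < 3)
      stop("evaluation subset '", label, "' has fewer than 3 observed accessions")
    list(subset = label, n = length(set),
         accuracy = stats::cor(fit$u_hat[set], obs[set]))
  }
  structure(
    list(trait = trait,
         repeated = one(repeated_set, "repeated"),
         new = one(new_set, "new"),
         fit = fit),
    class = "forward_validation_result"
  )
}

#' @export
print.forward_validation_result <- function(x, ...) {
  cat(sprintf("<forward_validation> %s: repeated r = %.3f (n = %d), new r = %.3f (n = %d)\n",
              x$trait, x$repeated$accuracy, x$repeated$n,
              x$new$accuracy, x$new$n))
  invisible(x)
}

#' Phenotypic correlations between environments
#'
#' Pearson correlation of observed accession means between every pair of
#' environments, over the accessions phenotyped in both. Pairs with fewer
#' than `min_shared` common accessions are flagged `NA` rather than
#' raising an error.
#'
#' @param pt phenotype table
#' @param trait trait label
#' @param min_shared minimum shared accessions per pair (default 3)
#' @return symmetric correlation matrix with unit diagonal, environments
#'   as dimnames
#' @export
phenotypic_correlation <- function(pt, trait, min_shared = 3) {
  pt <- as_phenotype_table(pt)
  pt <- pt[pt$trait == trait, , drop = FALSE]
  envs <- sort(unique(pt$env_id))
  if (length(envs) < 2) stop("need at least 2 environments")
  means <- lapply(stats::setNames(envs, envs),
                  function(e) accession_means(pt, trait, e))
  pair_cor_matrix(means, min_shared)
}

#' Genetic correlations between environments
#'
#' Fits the single-intercept GBLUP model separately within each
#' environment and correlates the resulting estimated genotypic values
#' between environment pairs over the accessions phenotyped in both —
#' the BLUP-based analogue of the phenotypic correlation, with
#' environment-specific noise shrunk away.
#'
#' @inheritParams phenotypic_correlation
#' @param grm GRM covering the phenotyped accessions
#' @return symmetric correlation matrix with unit diagonal
#' @export
genetic_correlation <- function(pt, grm, trait, min_shared = 3) {
  pt <- as_phenotype_table(pt)
  pt <- pt[pt$trait == trait, , drop = FALSE]
  envs <- sort(unique(pt$env_id))
  if (length(envs) < 2) stop("need at least 2 environments")
  vals <- lapply(stats::setNames(envs, envs), function(e) {
    fit <- fit_gblup(pt, grm, trait, envs = e)
    tested <- unique(pt$accession_id[pt$env_id == e])
    fit$u_hat[tested]
  })
  pair_cor_matrix(vals, min_shared)
}

pair_cor_matrix <- function(vals, min_shared) {
  envs <- names(vals)
  out <- diag(1, length(envs))
  dimnames(out) <- list(envs, envs)
  for (i in seq_along(envs)) for (j in seq_len(i - 1)) {
    shared <- intersect(names(vals[[i]]), names(vals[[j]]))
    out[i, j] <- out[j, i] <-
      if (length(shared) < min_shared) NA_real_
      else stats::cor(vals[[i]][shared], vals[[j]][shared])
  }
  out
}
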