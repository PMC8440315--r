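#' Expected improvement over the incumbent best
#'
#' For a candidate whose genotypic value has predictive mean `m` and
#' standard deviation `s`, and incumbent best `M` (the maximum estimated
#' genotypic value among phenotyped accessions),
#' `EI = (m - M) * pnorm(z) + s * dnorm(z)` with `z = (m - M) / s`.
#' At `s = 0` the continuous limit `max(m - M, 0)` is returned. EI is the
#' expectation of `max(U - M, 0)` for `U ~ N(m, s^2)`: large when the
#' prediction is high, but also when it is uncertain.
#'
#' @param m predicted genotypic value(s)
#' @param s standard deviation(s) of the prediction, `>= 0` (recycled)
#' @param M incumbent best estimated genotypic value
#' @return expected improvement, same length as `m`
#' @export
expected_improvement <- function(m, s, M) {
  if (any(s < 0)) stop("standard deviation `s` must be non-negative")
  k <- pmax(length(m), length(s))
  m <- rep_len(m, k); s <- rep_len(s, k)
  ei <- pmax(m - M, 0)
  pos <- s > 0
  if (any(pos)) {
    z <- (m[pos] - M) / s[pos]
    ei[pos] <- (m[pos] - M) * stats::pnorm(z) + s[pos] * stats::dnorm(z)
  }
  ei
}

#' Genotypic-value standard deviations from the mixed-model equations
#'
#' Frequentist approximation of the conditional SD of each accession's
#' genotypic value given the phenotypes, ignoring fixed effects:
#' the square root of `diag((Z'Z / sigma_e^2 + G^{-1} / sigma_u^2)^{-1})`,
#' computed over every accession in the GRM. Unphenotyped accessions have
#' a zero `Z'Z` entry and, when unrelated, recover the prior SD
#' `sigma_u`. A 1e-6 diagonal ridge is applied before inverting a
#' numerically singular GRM.
#'
#' @param fit a `gblup_fit`
#' @param design optional [model_design()] (defaults to the one in `fit`)
#' @return named vector of standard deviations, one per GRM accession
#' @export
genotypic_sd_mme <- function(fit, design = fit$design) {
  stopifnot(fit$sigma2_u > 0, fit$sigma2_e > 0)
  Ginv <- grm_solve(design$grm)
  counts <- tabulate(design$z_idx, nbins = length(design$accession_ids))
  C <- Ginv / fit$sigma2_u
  diag(C) <- diag(C) + counts / fit$sigma2_e
  s <- sqrt(diag(chol2inv(chol(C))))
  names(s) <- design$accession_ids
  s
}

#' Gibbs sampler for Bayesian GBLUP
#'
#' Samples the posterior of `y = X b + Z u + e` with `u ~ N(0, G
#' sigma_u^2)`, a flat prior on `b`, and scaled-inverse-chi-square priors
#' on both variances (default df 5, scale set so the prior mode equals
#' half the sample variance of `y`). The default schedule — 6000
#' iterations, 1200 burn-in, thinning 5 — retains 960 draws of `u`.
#'
#' @param design a [model_design()]
#' @param n_iter total iterations
#' @param burn_in discarded iterations
#' @param thin keep one draw per `thin` iterations after burn-in
#' @param seed RNG seed
#' @param df_prior degrees of freedom of both variance priors
#' @return a `gblup_samples` object: `u` (retained draws x accessions),
#'   `sigma2_u`, `sigma2_e` (retained draws), and the schedule
#' @export
gibbs_gblup <- function(design, n_iter = 6000, burn_in = 1200, thin = 5,
                        seed = 1, df_prior = 5) {
  stopifnot(inherits(design, "model_design"))
  if (n_iter <= 0 || burn_in < 0 || thin <= 0 || burn_in >= n_iter)
    stop("invalid iteration schedule: need 0 <= burn_in < n_iter and thin > 0")
  set.seed(seed)
  y <- design$y; X <- design$X
  n <- length(y); q <- length(design$accession_ids); p <- ncol(X)
  Ginv <- grm_solve(design$grm)
  counts <- tabulate(design$z_idx, nbins = q)
  XtX_inv <- solve(crossprod(X))
  R_x <- chol(XtX_inv)

  nu <- df_prior
  S0 <- 0.5 * stats::var(y) * (nu + 2) / nu  # prior mode at half var(y)
  sigma2_u <- sigma2_e <- 0.5 * stats::var(y)
  u <- numeric(q)
  b <- numeric(p)

  n_keep <- length(seq(burn_in + thin, n_iter, by = thin))
  keep_u <- matrix(NA_real_, n_keep, q,
                   dimnames = list(NULL, design$accession_ids))
  keep_s2u <- keep_s2e <- numeric(n_keep)
  k <- 0L

  # Z' v accumulates record values per accession; Z u expands back
  zt <- function(v) {
    out <- numeric(q)
    agg <- rowsum(v, design$z_idx)
    out[as.integer(rownames(agg))] <- agg
    out
  }

  for (it in seq_len(n_iter)) {
    # b | rest
    r_b <- y - u[design$z_idx]
    b <- drop(XtX_inv %*% crossprod(X, r_b)) +
      drop(crossprod(R_x, stats::rnorm(p))) * sqrt(sigma2_e)
    # u | rest
    r_u <- y - drop(X %*% b)
    C <- Ginv / sigma2_u
    diag(C) <- diag(C) + counts / sigma2_e
    Ru <- chol(C)
    mu_u <- backsolve(Ru, forwardsolve(t(Ru), zt(r_u) / sigma2_e))
    u <- mu_u + backsolve(Ru, stats::rnorm(q))
    # variances | rest
    sigma2_u <- (drop(crossprod(u, Ginv %*% u)) + nu * S0) /
      stats::rchisq(1, nu + q)
    e <- r_u - u[design$z_idx]
    sigma2_e <- (sum(e^2) + nu * S0) / stats::rchisq(1, nu + n)

    if (it > burn_in && (it - burn_in) %% thin == 0) {
      k <- k + 1L
      keep_u[k, ] <- u
      keep_s2u[k] <- sigma2_u
      keep_s2e[k] <- sigma2_e
    }
  }
  structure(
    list(u = keep_u, sigma2_u = keep_s2u, sigma2_e = keep_s2e,
         n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed),
    class = "gblup_samples"
  )
}

#' @export
print.gblup_samples <- function(x, ...) {
  cat(sprintf("<gblup_samples> %d retained draws x %d accessions (%d iter, %d burn-in, thin %d)\n",
              nrow(x$u), ncol(x$u), x$n_iter, x$burn_in, x$thin))
  invisible(x)
}

#' Posterior standard deviations of genotypic values from MCMC draws
#'
#' @param samples a `gblup_samples` object (or a draws-by-accession matrix)
#' @return named vector of per-accession posterior SDs (n - 1 denominator)
#' @export
genotypic_sd_mcmc <- function(samples) {
  u <- if (inherits(samples, "gblup_samples")) samples$u else as.matrix(samples)
  if (nrow(u) < 2) stop("need at least 2 retained draws to estimate posterior SDs")
  apply(u, 2, stats::sd)
}

#' Assemble expected-improvement candidates from a fit
#'
#' Joins PGVs with their uncertainty and computes EI against the incumbent
#' `M`, the maximum estimated genotypic value among tested (phenotyped)
#' accessions. By default only untested accessions are scored — the
#' selection use case; `include_tested = TRUE` scores everyone for
#' diagnostics.
#'
#' @param fit a `gblup_fit`
#' @param sd named per-accession SDs, from [genotypic_sd_mme()] or
#'   [genotypic_sd_mcmc()]
#' @param incumbent override for `M`
#' @param include_tested score tested accessions too?
#' @return data frame: `accession_id`, `m`, `s`, `z`, `ei`
#' @export
ei_candidates <- function(fit, sd, incumbent = NULL, include_tested = FALSE) {
  u <- fit$u_hat
  M <- if (is.null(incumbent)) max(u[names(u) %in% fit$tested_ids]) else incumbent
  ids <- if (include_tested) names(u) else setdiff(names(u), fit$tested_ids)
  if (length(ids) == 0) stop("no candidate accessions to score")
  if (!all(ids %in% names(sd))) stop("`sd` does not cover all candidates")
  m <- u[ids]; s <- sd[ids]
  data.frame(
    accession_id = ids, m = unname(m), s = unname(s),
    z = unname(ifelse(s > 0, (m - M) / s, sign(m - M) * Inf)),
    ei = unname(expected_improvement(m, s, M)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Rank scores and select the top k
#'
#' Deterministic: descending score, ties broken by ascending accession id.
#'
#' @param scores named numeric vector (accession -> score)
#' @param k list length (default 20)
#' @param exclude accession ids barred from selection (e.g. the training
#'   set)
#' @param criterion,source labels carried into the result
#' @return a `selection_result`: data frame `accession_id`, `score`,
#'   `rank`, with `criterion`, `source` and `k` attributes
#' @export
rank_and_select <- function(scores, k = 20, exclude = character(),
                            criterion = "PGV", source = "") {
  if (is.null(names(scores))) stop("`scores` must be named by accession id")
  scores <- scores[!names(scores) %in% exclude]
  if (k > length(scores))
    stop("k = ", k, " exceeds the ", length(scores), " eligible accessions")
  ord <- order(-scores, names(scores))[seq_len(k)]
  structure(
    data.frame(accession_id = names(scores)[ord],
               score = unname(scores[ord]),
               rank = seq_len(k),
               row.names = NULL, stringsAsFactors = FALSE),
    criterion = criterion, source = source, k = k,
    class = c("selection_result", "data.frame")
  )
}

#' Merge selection lists with overlap accounting
#'
#' Bookkeeping for top-k lists made per criterion, site and trait: the
#' union of selected accessions, its size, and the pairwise overlap
#' matrix |L_i intersect L_j| (two 20-lists sharing 16 accessions merge
#' into 24).
#'
#' @param ... `selection_result` objects, or a single list of them
#' @return list: `accessions` (sorted union), `n_union`, `overlap`
#'   (labelled pairwise count matrix)
#' @export
merge_selections <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && !inherits(lists[[1]], "selection_result"))
    lists <- lists[[1]]
  if (length(lists) < 2) stop("need at least 2 selection lists to merge")
  ids <- lapply(lists, function(l) l$accession_id)
  labels <- vapply(seq_along(lists), function(i) {
    lab <- paste(attr(lists[[i]], "criterion"), attr(lists[[i]], "source"))
    if (nchar(trimws(lab)) == 0) paste0("list", i) else trimws(lab)
  }, "")
  labels <- make.unique(labels)
  ov <- outer(seq_along(ids), seq_along(ids),
              Vectorize(function(i, j) length(intersect(ids[[i]], ids[[j]]))))
  dimnames(ov) <- list(labels, labels)
  all_ids <- sort(unique(unlist(ids)))
  list(accessions = all_ids, n_union = length(all_ids), overlap = ov)
}

#' Select a control set at equally spaced ranks
#'
#' Sorts candidates by estimated genotypic value (ascending; ties by
#' accession id) and picks `n_controls` ranks evenly spanning the full
#' range, first and last rank included — giving a check set with wide
#' phenotypic and genetic variation rather than a top slice.
#'
#' @param estimated_values named numeric vector (accession -> estimated
#'   genotypic value)
#' @param n_controls number of controls (>= 2)
#' @return character vector of selected accession ids, in ascending value
#'   order
#' @export
select_controls_equally_spaced <- function(estimated_values, n_controls) {
  if (n_controls < 2) stop("n_controls must be at least 2")
  n <- length(estimated_values)
  if (n_controls > n)
    stop("n_controls = ", n_controls, " exceeds the ", n, " candidates")
  ord <- order(estimated_values, names(estimated_values))
  ranks <- unique(round(seq(1, n, length.out = n_controls)))
  names(estimated_values)[ord][ranks]
}

#' Write a selection report TSV
#'
#' One row per candidate: PGV, SD, EI, rank under the requested criterion
#' and a selected flag.
#'
#' @param candidates an [ei_candidates()] data frame
#' @param selected a `selection_result`
#' @param path output path
#' @param trait,training_sites labels recorded in the report
#' @export
write_selection_tsv <- function(candidates, selected, path,
                                trait = "", training_sites = "") {
  out <- data.frame(
    accession_id = candidates$accession_id,
    criterion = attr(selected, "criterion"),
    trait = trait, training_sites = training_sites,
    pgv = candidates$m, sd = candidates$s, ei = candidates$ei,
    rank = match(candidates$accession_id, selected$accession_id),
    selected = candidates$accession_id %in% selected$accession_id,
    stringsAsFactors = FALSE
  )
  out <- out[order(!out$selected, out$rank, -out$pgv), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
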