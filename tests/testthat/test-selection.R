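test_that("expected improvement matches its closed-form limits", {
  expect_equal(expected_improvement(0, 1, 0), dnorm(0), tolerance = 1e-12)
  expect_equal(expected_improvement(-10, 1e-9, 0), 0, tolerance = 1e-12)
  expect_equal(expected_improvement(c(3, -2), 0, 1), c(2, 0))  # s = 0 limit
  expect_error(expected_improvement(1, -0.5, 0), "non-negative")
})

test_that("EI is monotone in mean and in uncertainty", {
  ms <- seq(-3, 3, length.out = 41)
  for (s in c(0.2, 1, 4))
    expect_true(all(diff(expected_improvement(ms, s, 0)) > 0))
  # s grid bounded away from 0 so dEI/ds = dnorm(z) stays representable
  ss <- seq(0.5, 5, length.out = 41)
  for (m in c(-2, 0, 2))
    expect_true(all(diff(expected_improvement(m, ss, 0)) > 0))
  # constant uncertainty: EI ordering is exactly the PGV ordering
  set.seed(1)
  m <- rnorm(50)
  expect_equal(order(expected_improvement(m, 0.7, 0.5)), order(m))
})

test_that("MME genotypic SDs satisfy the scalar closed forms", {
  n <- 12
  G <- identity_grm(n)
  # accessions 1..3 observed with 1, 2, 3 replicates; the rest unobserved
  pt <- make_pt(c("A01", "A02", "A02", "A03", "A03", "A03"),
                c(1, 2, 1.5, 0.3, 0.5, 0.1),
                rep = c(1, 1, 2, 1, 2, 3))
  d <- model_design(pt, G, "TR")
  fake_fit <- list(sigma2_u = 2.5, sigma2_e = 1.3, design = d)
  s <- genotypic_sd_mme(fake_fit)
  for (r in 1:3)
    expect_equal(unname(s[sprintf("A%02d", r)]),
                 sqrt(1 / (r / 1.3 + 1 / 2.5)), tolerance = 1e-12)
  # unobserved, unrelated: prior SD sigma_u
  expect_equal(unname(s["A09"]), sqrt(2.5), tolerance = 1e-12)
})

test_that("Eq-7 SDs equal joint-Gaussian conditional SDs", {
  set.seed(10)
  for (i in 1:4) {
    n <- sample(8:20, 1)
    G <- unclass(random_grm(n))
    counts <- sample(0:3, n, replace = TRUE)
    z_idx <- rep(seq_len(n), counts)
    s2u <- runif(1, 0.5, 3); s2e <- runif(1, 0.5, 3)
    d <- list(grm = G, z_idx = z_idx,
              accession_ids = rownames(G))
    s <- genotypic_sd_mme(list(sigma2_u = s2u, sigma2_e = s2e, design = d))
    Su <- s2u * G
    Z <- matrix(0, length(z_idx), n); Z[cbind(seq_along(z_idx), z_idx)] <- 1
    cond <- Su - Su %*% t(Z) %*%
      solve(Z %*% Su %*% t(Z) + diag(s2e, nrow(Z)), Z %*% Su)
    expect_equal(unname(s), unname(sqrt(diag(cond))), tolerance = 1e-8)
  }
})

test_that("Gibbs sampler obeys its schedule and is seed-deterministic", {
  sim <- quick_sim(n_pool = 30, n_train = 25, n_markers = 60, seed = 12)
  d <- model_design(sim$pt, sim$grm, "STW")
  s1 <- gibbs_gblup(d, n_iter = 600, burn_in = 120, thin = 5, seed = 99)
  expect_equal(nrow(s1$u), (600 - 120) / 5)
  s2 <- gibbs_gblup(d, n_iter = 600, burn_in = 120, thin = 5, seed = 99)
  expect_identical(s1$u, s2$u)
  s3 <- gibbs_gblup(d, n_iter = 600, burn_in = 120, thin = 5, seed = 100)
  expect_false(identical(s1$u, s3$u))
  expect_error(gibbs_gblup(d, n_iter = 100, burn_in = 200), "schedule")
  # default schedule retains (6000 - 1200) / 5 = 960 draws
  expect_equal(length(seq(1200 + 5, 6000, by = 5)), 960)
})

test_that("MCMC SDs follow the sample-SD definition", {
  draws <- matrix(c(1, 1, 1, 2, 5, 2), nrow = 3,
                  dimnames = list(NULL, c("A", "B")))
  s <- genotypic_sd_mcmc(draws)
  expect_equal(unname(s["A"]), 0)
  expect_equal(unname(genotypic_sd_mcmc(draws[1:2, ])["B"]),
               abs(2 - 5) / sqrt(2))
  expect_error(genotypic_sd_mcmc(draws[1, , drop = FALSE]), "at least 2")
})

test_that("ei_candidates scores untested accessions against the tested incumbent", {
  sim <- quick_sim(n_pool = 60, n_train = 40, n_markers = 100, h2 = 0.8,
                   seed = 13)
  fit <- fit_gblup(sim$pt, sim$grm, "STW")
  s <- genotypic_sd_mme(fit)
  cand <- ei_candidates(fit, s)
  expect_equal(nrow(cand), 20)
  expect_false(any(cand$accession_id %in% fit$tested_ids))
  M <- max(fit$u_hat[names(fit$u_hat) %in% fit$tested_ids])
  expect_equal(cand$ei,
               expected_improvement(cand$m, cand$s, M), tolerance = 1e-12)
  all_cand <- ei_candidates(fit, s, include_tested = TRUE)
  expect_equal(nrow(all_cand), 60)
})

test_that("rank_and_select is a deterministic top-k with id tie-breaks", {
  set.seed(4)
  scores <- setNames(round(rnorm(30), 2), sprintf("A%02d", 1:30))
  sel <- rank_and_select(scores, k = 10)
  ord <- order(-scores, names(scores))
  expect_equal(sel$accession_id, names(scores)[ord][1:10])  # sort oracle
  expect_equal(sel$rank, 1:10)

  full <- rank_and_select(scores, k = 30)
  expect_equal(full$accession_id, names(scores)[ord])

  tied <- setNames(rep(1, 5), c("B", "A", "E", "C", "D"))
  expect_equal(rank_and_select(tied, k = 3)$accession_id, c("A", "B", "C"))

  expect_equal(nrow(rank_and_select(scores, k = 10,
                                    exclude = names(scores)[1:15])), 10)
  expect_false(any(rank_and_select(scores, k = 10,
                                   exclude = "A01")$accession_id == "A01"))
  expect_error(rank_and_select(scores, k = 31), "exceeds")
})

test_that("merge_selections does the union and overlap bookkeeping", {
  mk <- function(ids, crit, src) rank_and_select(
    setNames(seq_along(ids), ids), k = length(ids),
    criterion = crit, source = src)
  a <- mk(sprintf("X%02d", 1:20), "PGV", "STW/Anjiro")
  b <- mk(sprintf("X%02d", 1:20), "EI", "STW/Anjiro")
  same <- merge_selections(a, b)
  expect_equal(same$n_union, 20)
  expect_equal(unname(same$overlap[1, 2]), 20)

  c2 <- mk(sprintf("Y%02d", 1:20), "EI", "STW/Behenjy")
  disjoint <- merge_selections(a, c2)
  expect_equal(disjoint$n_union, 40)
  expect_equal(unname(disjoint$overlap[1, 2]), 0)

  # two 20-lists sharing 16 accessions merge into 24
  d2 <- mk(c(sprintf("X%02d", 1:16), sprintf("Z%02d", 1:4)), "EI", "STW/Anjiro")
  partial <- merge_selections(a, d2)
  expect_equal(unname(partial$overlap[1, 2]), 16)
  expect_equal(partial$n_union, 24)

  expect_error(merge_selections(a), "at least 2")
})

test_that("equally spaced controls span the estimated-value distribution", {
  vals10 <- setNames(rnorm(10), sprintf("A%02d", 1:10))
  picks <- select_controls_equally_spaced(vals10, 2)
  expect_equal(picks, names(sort(vals10))[c(1, 10)])  # endpoints

  set.seed(6)
  vals <- setNames(rnorm(523), sprintf("A%03d", 1:523))
  ctl <- select_controls_equally_spaced(vals, 23)
  expect_length(ctl, 23)
  ranks <- match(ctl, names(sort(vals)))
  expect_true(all(diff(ranks) %in% c(23, 24)))
  # span oracle: the control value range equals the candidate range
  expect_equal(range(vals[ctl]), range(vals))

  expect_error(select_controls_equally_spaced(vals, 1), "at least 2")
  expect_error(select_controls_equally_spaced(vals10, 11), "exceeds")
})
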