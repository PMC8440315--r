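test_that("cross-validation nails the noiseless limit and the null", {
  # noiseless limit: held-out accuracy is capped by the genomic information,
  # so keep the marker count well below n (effective dimension << training n)
  sim <- quick_sim(n_pool = 300, n_train = 300, n_markers = 40,
                   h2 = 1 - 1e-6, seed = 21)
  cv <- kfold_cv(sim$pt, sim$grm, "STW", "E1", k = 5, repeats = 2, seed = 1)
  expect_gt(cv$mean_accuracy, 0.9)

  # pure noise: shuffle phenotypes against genotypes
  noise <- quick_sim(n_pool = 150, n_train = 150, n_markers = 300,
                     h2 = 0.5, seed = 22)
  pt0 <- noise$pt
  set.seed(5)
  pt0$value <- rnorm(nrow(pt0))
  cv0 <- kfold_cv(pt0, noise$grm, "STW", "E1", k = 5, repeats = 10, seed = 2)
  expect_lt(abs(cv0$mean_accuracy), 0.1)
})

test_that("cross-validation is reproducible and respects fold contracts", {
  sim <- quick_sim(n_pool = 100, n_train = 100, n_markers = 200, seed = 23)
  cv1 <- kfold_cv(sim$pt, sim$grm, "STW", "E1", k = 5, repeats = 3, seed = 7)
  cv2 <- kfold_cv(sim$pt, sim$grm, "STW", "E1", k = 5, repeats = 3, seed = 7)
  expect_identical(cv1$accuracies, cv2$accuracies)
  expect_equal(cv1$sd_accuracy, sd(cv1$accuracies))
  expect_error(kfold_cv(sim$pt, sim$grm, "STW", "E1", k = 60),
               "at least 2k")
  # per-fold aggregation is a valid alternative summary
  cv3 <- kfold_cv(sim$pt, sim$grm, "STW", "E1", k = 5, repeats = 3, seed = 7,
                  aggregate = "per_fold")
  expect_true(abs(cv3$mean_accuracy - cv1$mean_accuracy) < 0.2)
})

test_that("forward validation transfers signal if and only if environments correlate", {
  # degenerate reuse: test set = training set; an empty new set errors
  sim <- quick_sim(n_pool = 120, n_train = 100, n_markers = 250, h2 = 0.6,
                   seed = 31)
  train_ids <- sim$truth$train_ids
  expect_error(
    forward_validation(sim$pt, sim$pt, sim$grm, "STW",
                       repeated_set = train_ids, new_set = character(0)),
    "fewer than 3")
  # with a dummy observed new set, repeated accuracy equals the in-sample
  # correlation of u_hat with the phenotype means
  fake_new <- setdiff(rownames(sim$grm), train_ids)[1:5]
  test_pt <- rbind(sim$pt, phenotype_accessions(sim$truth, fake_new,
                                                n_reps = 1, seed = 77))
  fv_self <- forward_validation(sim$pt, test_pt, sim$grm, "STW",
                                repeated_set = train_ids, new_set = fake_new)
  fit <- fit_gblup(sim$pt, sim$grm, "STW")
  obs <- tapply(sim$pt$value, sim$pt$accession_id, mean)
  expect_equal(fv_self$repeated$accuracy,
               cor(fit$u_hat[names(obs)], obs), tolerance = 1e-10)
  expect_gt(fv_self$repeated$accuracy, 0)

  two_env <- function(rho, seed) {
    cfg <- sim_config(n_pool = 250, n_train = 150, n_markers = 500,
                      n_qtl = 500, h2_per_env = c(Y1 = 0.5, Y2 = 0.5),
                      env_intercepts = c(Y1 = 0, Y2 = 10),
                      genetic_corr = rho, n_reps = 1, missing_rate = 0,
                      seed = seed)
    g <- simulate_genotypes(cfg)
    sim2 <- simulate_phenotypes(g, cfg)
    pt <- sim2$phenotypes
    G <- compute_grm(g)
    train_pt <- pt[pt$env_id == "Y1", ]
    # year 2 phenotypes both the repeats and a disjoint new set
    train_acc <- unique(train_pt$accession_id)
    pool <- rownames(G)
    new_ids <- setdiff(pool, train_acc)[1:50]
    test_pt <- rbind(pt[pt$env_id == "Y2", ],
                     phenotype_accessions(sim2$truth, new_ids, n_reps = 1,
                                          seed = seed + 500))
    test_pt <- test_pt[test_pt$env_id == "Y2", ]
    forward_validation(train_pt, test_pt, G, "STW",
                       repeated_set = train_acc, new_set = new_ids)
  }
  acc_hi <- vapply(1:8, function(s) two_env(0.9, s)$new$accuracy, 0)
  expect_gt(mean(acc_hi), 0.2)
  acc_null <- vapply(1:8, function(s) two_env(0, 100 + s)$new$accuracy, 0)
  expect_lt(abs(mean(acc_null)), 0.1)

  fv <- two_env(0.9, 1)
  expect_gt(fv$repeated$accuracy, fv$new$accuracy - 1)  # both defined
  expect_error(
    forward_validation(sim$pt, sim$pt, sim$grm, "STW",
                       repeated_set = train_ids, new_set = train_ids[1:5]),
    "disjoint")
})

test_that("phenotypic correlations behave on duplicated, null and attenuated pairs", {
  sim <- quick_sim(n_pool = 100, n_train = 80, n_markers = 200, seed = 41)
  dup <- sim$pt
  dup2 <- dup; dup2$env_id <- "E1copy"
  r <- phenotypic_correlation(rbind(dup, dup2), "STW")
  expect_equal(unname(r["E1", "E1copy"]), 1, tolerance = 1e-12)
  expect_equal(diag(r), c(E1 = 1, E1copy = 1))
  expect_equal(r, t(r))

  # independent noise in two environments
  set.seed(3)
  ids <- sprintf("A%03d", 1:200)
  pt_null <- rbind(make_pt(ids, rnorm(200), env_id = "P"),
                   make_pt(ids, rnorm(200), env_id = "Q"))
  rn <- phenotypic_correlation(pt_null, "TR")
  expect_lt(abs(rn["P", "Q"]), 0.15)

  # attenuation: phenotypic r ~ genetic_corr * h2 = 0.6 * 0.5 = 0.30
  rp <- vapply(1:20, function(s) {
    cfg <- sim_config(n_pool = 200, n_train = 200, n_markers = 300,
                      n_qtl = 300, h2_per_env = c(U = 0.5, V = 0.5),
                      env_intercepts = c(U = 0, V = 0), genetic_corr = 0.6,
                      n_reps = 1, missing_rate = 0, seed = s)
    sim2 <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
    phenotypic_correlation(sim2$phenotypes, "STW")["U", "V"]
  }, 0)
  expect_lt(abs(mean(rp) - 0.30), 0.08)

  # insufficient overlap: flagged NA, not an error
  pt_dis <- rbind(make_pt(ids[1:50], rnorm(50), env_id = "P"),
                  make_pt(ids[51:100], rnorm(50), env_id = "Q"))
  expect_true(is.na(phenotypic_correlation(pt_dis, "TR")["P", "Q"]))
})

test_that("genetic correlations shrink noise and sit above phenotypic ones", {
  sim <- quick_sim(n_pool = 80, n_train = 60, n_markers = 150, seed = 51)
  dup <- sim$pt; dup2 <- dup; dup2$env_id <- "E1copy"
  rg <- genetic_correlation(rbind(dup, dup2), sim$grm, "STW")
  expect_equal(unname(rg["E1", "E1copy"]), 1, tolerance = 1e-10)

  one <- function(s) {
    cfg <- sim_config(n_pool = 200, n_train = 200, n_markers = 400,
                      n_qtl = 400, h2_per_env = c(U = 0.8, V = 0.8),
                      env_intercepts = c(U = 0, V = 0), genetic_corr = 0.6,
                      n_reps = 2, missing_rate = 0, seed = s)
    g <- simulate_genotypes(cfg)
    sim2 <- simulate_phenotypes(g, cfg)
    G <- compute_grm(g)
    c(gen = unname(genetic_correlation(sim2$phenotypes, G, "STW")["U", "V"]),
      phen = unname(phenotypic_correlation(sim2$phenotypes, "STW")["U", "V"]))
  }
  res <- vapply(1:8, one, c(gen = 0, phen = 0))
  expect_gt(mean(res["gen", ] - res["phen", ]), 0)
})
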