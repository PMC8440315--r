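#' Assemble and validate a pipeline configuration
#'
#' A configuration describes one full donor-selection run: where the
#' genotypes and phenotypes come from (either file paths or a simulation
#' block — exactly one of the two), marker filter thresholds, the traits
#' and environments to model, the selection block (criteria, list length
#' `k`, whether tested accessions are excluded, control-set size,
#' uncertainty method) and the evaluation block (CV folds/repeats). All
#' randomness flows from the single root `seed`, expanded into fixed
#' per-stage offsets.
#'
#' @param x a named list, or path to a JSON file with the same structure
#' @return validated `pipeline_config` list
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  stopifnot(is.list(x))
  has_sim <- !is.null(x$simulate)
  has_paths <- !is.null(x$genotypes) || !is.null(x$phenotypes)
  if (has_sim == has_paths)
    stop("config must contain exactly one of: a `simulate` block, or `genotypes` + `phenotypes` paths")
  defaults <- list(
    filter = list(max_missing = 0.05, min_maf = 0.025),
    selection = list(criteria = c("PGV", "EI"), k = 20, exclude_tested = TRUE,
                     n_controls = 0, sd_method = "mme"),
    evaluation = list(cv_k = 10, cv_repeats = 10),
    cycles = 1, seed = 1
  )
  for (nm in names(defaults)) {
    if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      x[[nm]] <- utils::modifyList(defaults[[nm]], x[[nm]])
  }
  if (has_sim) {
    sim <- x$simulate
    if (!is.null(sim$h2_per_env)) sim$h2_per_env <- unlist(sim$h2_per_env)
    if (!is.null(sim$env_intercepts)) sim$env_intercepts <- unlist(sim$env_intercepts)
    if (!is.null(sim$maf_range)) sim$maf_range <- unlist(sim$maf_range)
    if (is.null(sim$seed)) sim$seed <- x$seed
    x$simulate <- do.call(sim_config, sim)
  }
  if (!x$selection$sd_method %in% c("mme", "mcmc"))
    stop("selection.sd_method must be 'mme' or 'mcmc'")
  if (x$cycles > 1 && !has_sim)
    stop("multi-cycle runs need the simulation block (new phenotypes must be generated)")
  structure(x, class = "pipeline_config")
}

stage_msg <- function(log, stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full donor-selection pipeline
#'
#' Executes, in order: data acquisition (simulate or load), marker
#' filtering, mean imputation, GRM construction, per-trait GBLUP fits for
#' each configured environment, PGV/EI criteria with uncertainty, top-k
#' selection with overlap bookkeeping, equally spaced controls, and
#' repeated k-fold cross-validation. With `cycles > 1` (simulation mode),
#' each cycle phenotypes the newly selected accessions from the frozen
#' simulated truth, augments the training set, refits and reselects.
#' Every artifact is written under `out_dir` and listed, with an MD5
#' checksum, in `manifest.json`; identical configurations reproduce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()] (or list / JSON path coercible to
#'   one)
#' @param out_dir output directory (created if absent)
#' @param stop_after optionally halt after one of `"simulate"`,
#'   `"filter"`, `"grm"` or `"select"` — the CLI's per-stage subcommands
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config, out_dir, stop_after = NULL) {
  config <- pipeline_config(config)
  if (!is.null(stop_after))
    stop_after <- match.arg(stop_after, c("simulate", "filter", "grm", "select"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  put <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    artifacts[[length(artifacts) + 1]] <<- path
    path
  }

  cfg_path <- file.path(out_dir, "config.json")
  cfg_plain <- unclass(config)
  if (!is.null(cfg_plain$simulate))
    cfg_plain$simulate <- lapply(unclass(cfg_plain$simulate), function(x)
      if (is.null(names(x))) x else as.list(x))
  jsonlite::write_json(cfg_plain, cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, cfg_path)
  stages <- character(0)
  finish <- function(extra = list()) {
    manifest <- c(list(
      package = "gsei",
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      stages = stages,
      artifacts = lapply(artifacts, function(p)
        list(file = basename(p), md5 = unname(tools::md5sum(p))))
    ), extra)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }

  # --- acquire -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    g <- simulate_genotypes(config$simulate)
    sim <- simulate_phenotypes(g, config$simulate)
    pt <- sim$phenotypes; truth <- sim$truth
    put(g, "genotypes_raw.tsv", write_dosage_tsv)
    put(pt, "phenotypes.csv", write_phenotypes_csv)
    put(truth, "truth.tsv", write_truth_tsv)
    stage_msg(NULL, "simulate", "%d accessions x %d markers, %d phenotype records",
              nrow(g$dosages), ncol(g$dosages), nrow(pt))
    stages <- c(stages, "simulate")
  } else {
    g <- read_genotypes(config$genotypes)
    pt <- read_phenotypes_csv(config$phenotypes)
    stage_msg(NULL, "load", "%d accessions x %d markers, %d phenotype records",
              nrow(g$dosages), ncol(g$dosages), nrow(pt))
    stages <- c(stages, "load")
  }
  if (identical(stop_after, "simulate")) return(finish())

  # --- filter / impute / grm ----------------------------------------------
  g <- filter_markers(g, config$filter$max_missing, config$filter$min_maf)
  g <- impute_mean(g)
  put(g, "genotypes_filtered.tsv", write_dosage_tsv)
  stages <- c(stages, "filter")
  if (identical(stop_after, "filter")) return(finish())
  G <- compute_grm(g)
  put(G, "grm.tsv", write_grm_tsv)
  stage_msg(NULL, "grm", "%d x %d, mean diagonal %.3f", nrow(G), ncol(G),
            mean(diag(unclass(G))))
  stages <- c(stages, "grm")
  if (identical(stop_after, "grm")) return(finish())

  traits <- config$model$traits %||% unique(pt$trait)
  envs <- config$model$envs %||% unique(pt$env_id)
  sel_cfg <- config$selection

  cycle_sizes <- integer(0)
  selected_by_cycle <- list()
  for (cycle in seq_len(config$cycles)) {
    tag <- if (config$cycles > 1) sprintf("_cycle%d", cycle) else ""
    cycle_sizes <- c(cycle_sizes, length(unique(pt$accession_id)))
    all_lists <- list()
    for (trait in traits) {
      trait_envs <- intersect(envs, unique(pt$env_id[pt$trait == trait]))
      for (env in trait_envs) {
        design <- model_design(pt, G, trait, envs = env)
        fit <- fit_gblup_reml(design)
        fit_report <- list(trait = trait, env = env, beta = as.list(fit$beta),
                           sigma2_u = fit$sigma2_u, sigma2_e = fit$sigma2_e,
                           reml_loglik = fit$reml_loglik)
        put(fit_report, sprintf("fit_%s_%s%s.json", trait, env, tag),
            function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
        put(data.frame(accession_id = names(fit$u_hat), u_hat = unname(fit$u_hat)),
            sprintf("u_hat_%s_%s%s.tsv", trait, env, tag),
            function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
        stage_msg(NULL, "fit", "%s @ %s: sigma2_u = %.4g, sigma2_e = %.4g",
                  trait, env, fit$sigma2_u, fit$sigma2_e)

        sdv <- if (sel_cfg$sd_method == "mcmc") {
          genotypic_sd_mcmc(gibbs_gblup(design, seed = config$seed + 17L))
        } else genotypic_sd_mme(fit, design)
        cand <- ei_candidates(fit, sdv,
                              include_tested = !isTRUE(sel_cfg$exclude_tested))
        exclude <- if (isTRUE(sel_cfg$exclude_tested)) fit$tested_ids else character(0)
        for (crit in sel_cfg$criteria) {
          scores <- stats::setNames(
            if (crit == "EI") cand$ei else cand$m, cand$accession_id)
          sel <- rank_and_select(scores, k = sel_cfg$k, exclude = exclude,
                                 criterion = crit,
                                 source = paste(trait, env, sep = "/"))
          put(list(cand = cand, sel = sel),
              sprintf("selection_%s_%s_%s%s.tsv", crit, trait, env, tag),
              function(o, p) write_selection_tsv(o$cand, o$sel, p,
                                                 trait = trait, training_sites = env))
          all_lists[[length(all_lists) + 1]] <- sel
        }
        if (sel_cfg$n_controls >= 2) {
          egv <- predict_genotypic_values(fit, "tested")
          controls <- select_controls_equally_spaced(egv, sel_cfg$n_controls)
          put(data.frame(accession_id = controls),
              sprintf("controls_%s_%s%s.tsv", trait, env, tag),
              function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
        }
      }
    }
    merged <- if (length(all_lists) >= 2) merge_selections(all_lists)
    else list(accessions = all_lists[[1]]$accession_id,
              n_union = nrow(all_lists[[1]]), overlap = NULL)
    selected_by_cycle[[cycle]] <- merged$accessions
    if (!is.null(merged$overlap))
      put(data.frame(list_id = rownames(merged$overlap), merged$overlap,
                     check.names = FALSE),
          sprintf("selection_overlap%s.tsv", tag),
          function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
    stage_msg(NULL, "select", "cycle %d: %d accessions selected (union of %d lists)",
              cycle, merged$n_union, length(all_lists))
    stages <- c(stages, sprintf("select%s", tag))

    if (cycle < config$cycles) {
      newly <- setdiff(merged$accessions, unique(pt$accession_id))
      new_pt <- phenotype_accessions(
        truth, newly, n_reps = config$simulate$n_reps,
        trait = config$simulate$trait, seed = config$seed + 1000L + cycle)
      pt <- as_phenotype_table(rbind(pt, new_pt))
    }
  }
  if (identical(stop_after, "select"))
    return(finish(list(training_size_by_cycle = cycle_sizes,
                       selected_by_cycle = selected_by_cycle)))

  # --- evaluate ------------------------------------------------------------
  ev <- config$evaluation
  cv_rows <- list()
  for (trait in traits) for (env in intersect(envs, unique(pt$env_id[pt$trait == trait]))) {
    n_acc <- length(unique(pt$accession_id[pt$trait == trait & pt$env_id == env]))
    if (n_acc < 2 * ev$cv_k) next
    cv <- kfold_cv(pt, G, trait, env, k = ev$cv_k, repeats = ev$cv_repeats,
                   seed = config$seed + 29L)
    cv_rows[[length(cv_rows) + 1]] <- data.frame(
      trait = trait, env = env, protocol = "cv",
      mean_accuracy = cv$mean_accuracy, sd_accuracy = cv$sd_accuracy,
      n = cv$n_accessions)
    stage_msg(NULL, "evaluate", "CV %s @ %s: r = %.3f (SD %.3f)",
              trait, env, cv$mean_accuracy, cv$sd_accuracy)
  }
  if (length(cv_rows) > 0) {
    put(do.call(rbind, cv_rows), "evaluation.tsv",
        function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
    stages <- c(stages, "evaluate")
  }

  finish(list(training_size_by_cycle = cycle_sizes,
              selected_by_cycle = selected_by_cycle))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
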