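# End-to-end orchestration: simulate (or load) the three experiment
# tables, run every analysis stage in order, write tidy CSV outputs and a
# JSON run manifest. Identical config + seed gives byte-identical output.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  path
}

#' Run the full early-establishment analysis pipeline
#'
#' Executes, in order: data acquisition (seeded simulation via
#' [sim_config()] or CSV input paths), germination metrics and dormancy
#' classification with a scarification log-rank test, multi-soil outcome
#' rates / establishment matrix / logistic fit, pH x DAS trait derivation
#' with ANOVA per trait, and the integration stage (z-score PCA, Ward.D2
#' clustering, Spearman screen, ISI, per-soil recommendations, and the
#' dormancy-establishment correlation). Every stage fails fast with a
#' stage-named error; outputs and seeds are recorded in a JSON manifest.
#'
#' @param config Either a path to a YAML file or a list with optional
#'   entries: `seed` (integer, default 1), `simulate` (list of
#'   [sim_config()] overrides; used when no input paths are given),
#'   `inputs` (list with `germination`, `ordinal`, `growth` CSV paths),
#'   `k_clusters` (default 5), `top_n` (default 5),
#'   `bootstrap_reps` (default 100).
#' @param outdir Output directory (created if needed).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("[stage config] config file not found: %s", config),
           call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  k_clusters <- config$k_clusters %||% 5L
  top_n <- config$top_n %||% 5L
  boot_reps <- config$bootstrap_reps %||% 100L
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))

  # --- stage: data -----------------------------------------------------
  if (!is.null(config$inputs)) {
    germ <- .stage("load", {
      for (nm in c("germination", "ordinal", "growth"))
        if (is.null(config$inputs[[nm]]) || !file.exists(config$inputs[[nm]]))
          stop(sprintf("missing input CSV for '%s'", nm))
      read_table(config$inputs$germination, "germination")
    })
    ordinal <- .stage("load", read_table(config$inputs$ordinal, "ordinal"))
    growth <- .stage("load", read_table(config$inputs$growth, "growth"))
    cfg_sim <- NULL
  } else {
    cfg_sim <- .stage("simulate", do.call(sim_config, utils::modifyList(
      list(rng_seed = seed), as.list(config$simulate %||% list()))))
    germ <- .stage("simulate", simulate_germination(cfg_sim))
    ordinal <- .stage("simulate", simulate_soil_experiment(cfg_sim))
    growth <- .stage("simulate", simulate_ph_experiment(cfg_sim))
    paths$germination_csv <- .write_csv(germ, file.path(outdir, "germination.csv"))
    paths$ordinal_csv <- .write_csv(ordinal, file.path(outdir, "ordinal.csv"))
    paths$growth_csv <- .write_csv(growth, file.path(outdir, "growth.csv"))
  }

  # --- stage: germ-metrics ---------------------------------------------
  metrics <- .stage("germ-metrics", germination_metrics(germ))
  ns <- metrics[metrics$treatment == "NS", , drop = FALSE]
  dormancy <- .stage("germ-metrics", classify_dormancy(ns))
  trials <- as_germination_trials(germ)
  by_trt <- lapply(c(NS = "NS", S = "S"), function(trt) {
    ev <- lapply(trials[vapply(trials, function(tr) tr$treatment == trt,
                               TRUE)], trial_event_times)
    list(events = unlist(lapply(ev, `[[`, "events")),
         censored = unlist(lapply(ev, `[[`, "censored")))
  })
  logrank <- .stage("germ-metrics", logrank_test(by_trt))
  paths$germination_metrics_csv <-
    .write_csv(merge(metrics, dormancy[c("accession_id", "dormancy_class")],
                     by = "accession_id", all.x = TRUE),
               file.path(outdir, "germination_metrics.csv"))

  # --- stage: soil-outcomes --------------------------------------------
  rates <- .stage("soil-outcomes",
                  aggregate_rates(ordinal, c("species", "soil_code", "treatment")))
  est_mat <- .stage("soil-outcomes", establishment_matrix(ordinal))
  logistic <- .stage("soil-outcomes",
                     fit_logistic(ordinal, "established",
                                  ~ species + soil_code + treatment))
  paths$soil_rates_csv <- .write_csv(rates, file.path(outdir, "soil_rates.csv"))
  paths$establishment_matrix_csv <-
    .write_csv(data.frame(accession_id = rownames(est_mat), est_mat,
                          check.names = FALSE),
               file.path(outdir, "establishment_matrix.csv"))
  paths$logistic_csv <- .write_csv(logistic$coefficients,
                                   file.path(outdir, "logistic_establishment.csv"))

  # --- stage: ph-growth ------------------------------------------------
  traits <- .stage("ph-growth", derive_growth_traits(growth))
  fv <- filter_valid(traits)
  anovas <- lapply(c(hypocotyl_mm = "hypocotyl_mm", epicotyl_mm = "epicotyl_mm",
                     total_mm = "total_mm", ratio = "ratio"),
                   function(resp) .stage("ph-growth",
                     anova_two_way(fv$retained, resp)))
  anova_tab <- do.call(rbind, Map(function(tab, nm)
    cbind(trait = nm, tab), anovas, names(anovas)))
  contrasts <- .stage("ph-growth",
                      pairwise_contrasts(fv$retained, "total_mm", "ph_level",
                                         n_perm = 499L, rng_seed = seed + 7L))
  paths$growth_traits_csv <- .write_csv(traits, file.path(outdir, "growth_traits.csv"))
  paths$growth_anova_csv <- .write_csv(anova_tab, file.path(outdir, "growth_anova.csv"))
  paths$growth_contrasts_csv <- .write_csv(contrasts,
                                           file.path(outdir, "growth_contrasts.csv"))

  # --- stage: integrate ------------------------------------------------
  isi <- .stage("integrate",
                withCallingHandlers(compute_isi(isi_inputs(traits)),
                                    warning = function(w) {
                                      note(w); invokeRestart("muffleWarning")
                                    }))
  acc_rates <- aggregate_rates(ordinal, "accession_id")
  trait_tab <- merge(acc_rates[c("accession_id", "germination_rate",
                                 "cotyledon_rate", "establishment_rate")],
                     isi[c("accession_id", "est_mean", "length_mean",
                           "stability")], by = "accession_id")
  m <- as.matrix(trait_tab[, -1L])
  rownames(m) <- trait_tab$accession_id
  z <- .stage("integrate", withCallingHandlers(zscore_matrix(m),
                warning = function(w) { note(w); invokeRestart("muffleWarning") }))
  pca_res <- .stage("integrate", pca(z))
  clust <- .stage("integrate",
                  ward_cluster(z, k = min(k_clusters, nrow(z) - 1L),
                               bootstrap_reps = boot_reps,
                               rng_seed = seed + 11L))
  screen <- .stage("integrate",
                   spearman_screen(m, bootstrap_reps = 200L,
                                   rng_seed = seed + 13L))
  corr <- .stage("integrate", {
    dd <- ns[c("accession_id", "dds50", "dds50_censored")]
    common <- intersect(dd$accession_id, rownames(est_mat))
    if (length(common) >= 4L)
      correlate_dormancy_establishment(dd[dd$accession_id %in% common, ],
                                       est_mat[common, , drop = FALSE])
    else NULL
  })
  recs <- do.call(rbind, lapply(colnames(est_mat), function(soil)
    cbind(soil_code = soil,
          .stage("integrate", recommend_accessions(est_mat, isi, soil, top_n)))))
  paths$isi_csv <- .write_csv(isi, file.path(outdir, "isi.csv"))
  paths$pca_loadings_csv <-
    .write_csv(data.frame(trait = rownames(pca_res$loadings),
                          pca_res$loadings, check.names = FALSE),
               file.path(outdir, "pca_loadings.csv"))
  paths$pca_scores_csv <-
    .write_csv(data.frame(accession_id = rownames(pca_res$scores),
                          pca_res$scores, check.names = FALSE),
               file.path(outdir, "pca_scores.csv"))
  paths$correlations_csv <- .write_csv(screen, file.path(outdir, "correlations.csv"))
  if (!is.null(corr))
    paths$dormancy_correlation_csv <-
      .write_csv(corr, file.path(outdir, "dormancy_correlation.csv"))
  paths$recommendations_csv <- .write_csv(recs,
                                          file.path(outdir, "recommendations.csv"))
  clustering <- list(merge = clust$hclust$merge, height = clust$hclust$height,
                     labels = clust$hclust$labels,
                     cluster = as.list(clust$labels),
                     mean_silhouette = clust$mean_silhouette,
                     node_support = clust$node_support)
  paths$clustering_json <- file.path(outdir, "clustering.json")
  jsonlite::write_json(clustering, paths$clustering_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # --- manifest --------------------------------------------------------
  cfg_path <- file.path(outdir, "config_used.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- list(
    tool = paste("lupinest", as.character(utils::packageVersion("lupinest"))),
    config_digest = unname(tools::md5sum(cfg_path)),
    seeds = list(base = seed, exp1 = seed + 101L, exp2 = seed + 202L,
                 exp3 = seed + 303L, contrasts = seed + 7L,
                 cluster_bootstrap = seed + 11L, spearman = seed + 13L),
    row_counts = list(germination = nrow(germ), ordinal = nrow(ordinal),
                      growth = nrow(growth), growth_valid = nrow(fv$retained),
                      growth_excluded = fv$n_excluded,
                      accessions_isi = nrow(isi)),
    logrank = logrank,
    mean_silhouette = clust$mean_silhouette,
    outputs = paths,
    warnings = warnings_log
  )
  paths_exist <- vapply(unlist(paths), file.exists, TRUE)
  if (!all(paths_exist))
    stop(sprintf("[stage manifest] missing output(s): %s",
                 paste(names(paths_exist)[!paths_exist], collapse = ", ")),
         call. = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
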