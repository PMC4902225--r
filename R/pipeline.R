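#' Default end-to-end pipeline configuration
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return Nested configuration list with sections `simulate`, `features`,
#'   `stats` and `report`. Set `$input$feature_csv` (and optionally
#'   `$input$column_map`) to skip the audio stages and ingest an existing
#'   per-call measurement table instead.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(), # overrides for population_config()
    input = NULL,      # list(feature_csv =, column_map =) to skip audio
    features = list(prune_threshold = 0.95, n_per_bird = 5L, min_calls = 5L),
    stats = list(metric = "euclidean", standardize = "zscore",
                 n_perm = 999L, n_trees = 4999L,
                 factors = c("sex", "age", "variant"),
                 interactions = "sex:variant"),
    report = list(out_dir = NULL, make_plots = FALSE)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full acoustic-similarity analysis pipeline
#'
#' Orchestrates every stage: synthetic call generation (or feature-table
#' ingestion), spectrogram feature extraction, correlation pruning,
#' per-bird subsampling, permutational MANOVA of sex, age and call
#' variant with individual identity as the exchangeable unit,
#' unsupervised random-forest similarity with the within- versus
#' between-individual t-test, supervised feature-importance rankings,
#' and PCoA/NMDS ordination with group confidence ellipses. Every
#' statistic in the bundle records its metric, permutation count and
#' seed. With a fixed seed the whole bundle is reproducible.
#'
#' @param config A configuration list (see [pipeline_config]), a path to
#'   a YAML file with the same structure, or `NULL` for defaults.
#' @param seed Optional master seed overriding `config$seed`.
#' @param quiet Suppress per-stage messages.
#' @return A list of class `"pipeline_report"`: `manifest`, `features`
#'   (pruned, subsampled table), `prune_report`, `permanova`,
#'   `similarity`, `within_between`, `importance`, `pcoa_feat`,
#'   `pcoa_rf`, `nmds_rf`, `ellipses`, and `summary` (flat named list of
#'   the headline statistics).
#' @export
run_pipeline <- function(config = NULL, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(pipeline_config(), if (is.null(config)) list() else config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "configuration"
  on_fail <- function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    if (is.null(cfg$input)) {
      stage <- "simulate"
      sim_args <- cfg$simulate
      sim_args$seed <- cfg$seed
      pop_cfg <- do.call(population_config, sim_args)
      say("simulate: %d birds, seed %d", pop_cfg$n_birds, cfg$seed)
      gen <- generate_calls(pop_cfg)
      manifest <- gen$manifest
      stage <- "features"
      say("features: measuring %d clips", length(gen$clips))
      feats <- batch_features(gen$clips, manifest)
      n_failed <- nrow(attr(feats, "failures"))
      if (n_failed > 0) say("features: %d clip(s) failed and were skipped", n_failed)
    } else {
      stage <- "ingest"
      say("ingest: %s", cfg$input$feature_csv)
      feats <- read_feature_table(cfg$input$feature_csv, cfg$input$column_map)
      manifest <- feats[, intersect(metadata_columns(), names(feats)),
                        drop = FALSE]
    }

    stage <- "prune"
    pruned <- prune_correlated(feats, threshold = cfg$features$prune_threshold)
    say("prune: %d -> %d features", length(feature_columns(feats)),
        length(feature_columns(pruned$table)))

    stage <- "subsample"
    tab <- subsample_calls(pruned$table, n_per_bird = cfg$features$n_per_bird,
                           min_calls = cfg$features$min_calls,
                           seed = cfg$seed + 1L)
    say("subsample: %d calls from %d birds", nrow(tab),
        length(unique(tab$bird_id)))

    stage <- "permanova"
    D <- distance_matrix(tab, metric = cfg$stats$metric,
                         standardize = cfg$stats$standardize)
    design <- lapply(stats::setNames(cfg$stats$factors, cfg$stats$factors),
                     function(f) tab[[f]])
    # one pMANOVA per factor, with individual identity as the exchangeable
    # unit: bird-level factors (sex, age) permute whole birds as blocks
    perm_single <- lapply(stats::setNames(cfg$stats$factors, cfg$stats$factors),
                          function(f) {
      permanova_terms(D, design[f], nest_in = tab$bird_id,
                      n_perm = cfg$stats$n_perm, seed = cfg$seed + 2L)
    })
    perm_multi <- permanova_terms(D, design,
                                  interactions = cfg$stats$interactions,
                                  nest_in = tab$bird_id,
                                  n_perm = cfg$stats$n_perm,
                                  seed = cfg$seed + 3L)

    stage <- "rf-similarity"
    say("rf-similarity: %d trees", cfg$stats$n_trees)
    sim <- unsupervised_proximity(tab, n_trees = cfg$stats$n_trees,
                                  seed = cfg$seed + 4L)
    wb <- within_between_similarity(sim)

    stage <- "importance"
    importance <- list()
    for (f in cfg$stats$factors) {
      pf <- perm_single[[f]]$terms$p_value[1L]
      class_sizes <- table(tab[[f]])
      if (!is.na(pf) && pf <= 0.05 && length(class_sizes) >= 2L &&
          all(class_sizes >= 2L)) {
        importance[[f]] <- supervised_importance(tab, tab[[f]],
                                                 n_trees = cfg$stats$n_trees,
                                                 seed = cfg$seed + 5L)
      }
    }

    stage <- "ordination"
    pcoa_feat <- pcoa(D, k = 2L)
    D_rf <- similarity_to_distance(sim)
    pcoa_rf <- pcoa(D_rf, k = 2L)
    nmds_rf <- nmds(D_rf, k = 2L, seed = cfg$seed + 6L)
    ellipses <- group_ellipses(pcoa_feat, tab$sex, level = 0.99)

    stage <- "report"
    p_of <- function(r, term) {
      t <- r$terms
      t$p_value[match(term, t$term)]
    }
    f_of <- function(r, term) r$terms$pseudo_F[match(term, r$terms$term)]
    r2_of <- function(r, term) r$terms$r_squared[match(term, r$terms$term)]
    summary <- list(
      n_calls = nrow(tab),
      n_birds = length(unique(tab$bird_id)),
      n_features = length(feature_columns(tab)),
      metric = cfg$stats$metric,
      n_permutations = cfg$stats$n_perm,
      n_trees = cfg$stats$n_trees,
      seed = cfg$seed,
      version = as.character(utils::packageVersion("flightcallr")),
      sex_F = f_of(perm_single$sex, "sex"),
      sex_R2 = r2_of(perm_single$sex, "sex"),
      sex_p = p_of(perm_single$sex, "sex"),
      age_F = f_of(perm_single$age, "age"),
      age_R2 = r2_of(perm_single$age, "age"),
      age_p = p_of(perm_single$age, "age"),
      variant_F = f_of(perm_single$variant, "variant"),
      variant_R2 = r2_of(perm_single$variant, "variant"),
      variant_p = p_of(perm_single$variant, "variant"),
      sex_variant_F = f_of(perm_multi, "sex:variant"),
      sex_variant_R2 = r2_of(perm_multi, "sex:variant"),
      sex_variant_p = p_of(perm_multi, "sex:variant"),
      within_mean = mean(wb$within_means),
      between_mean = mean(wb$between_means),
      t_statistic = wb$t_statistic,
      t_df = wb$df,
      t_p = wb$p_value,
      nmds_stress = nmds_rf$stress
    )

    out_dir <- cfg$report$out_dir
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_feature_table(file.path(out_dir, "features.csv"), tab)
      utils::write.csv(pruned$report, file.path(out_dir, "prune_report.csv"),
                       row.names = FALSE)
      write_similarity_matrix(file.path(out_dir, "similarity.csv"), sim)
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      if (isTRUE(cfg$report$make_plots)) {
        grDevices::png(file.path(out_dir, "pcoa_sex.png"), 800, 800)
        plot_ordination(pcoa_feat, tab$sex, main = "PCoA by sex")
        grDevices::dev.off()
        grDevices::png(file.path(out_dir, "similarity_heatmap.png"), 800, 800)
        plot_similarity_heatmap(sim, main = "Call similarity by bird")
        grDevices::dev.off()
        grDevices::png(file.path(out_dir, "nmds_bird.png"), 800, 800)
        plot_ordination(nmds_rf, tab$bird_id, main = "NMDS by bird")
        grDevices::dev.off()
      }
    }

    structure(list(
      manifest = manifest, features = tab, prune_report = pruned$report,
      permanova = list(single = perm_single, multi = perm_multi),
      similarity = sim, within_between = wb, importance = importance,
      pcoa_feat = pcoa_feat, pcoa_rf = pcoa_rf, nmds_rf = nmds_rf,
      ellipses = ellipses, summary = summary, config = cfg
    ), class = "pipeline_report")
  }, error = on_fail)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Flight-call similarity analysis (%d calls, %d birds, %d features)\n",
              s$n_calls, s$n_birds, s$n_features))
  cat(sprintf("  pMANOVA  sex:     F = %.2f, R2 = %.3f, p = %.3g\n",
              s$sex_F, s$sex_R2, s$sex_p))
  cat(sprintf("           age:     F = %.2f, R2 = %.3f, p = %.3g\n",
              s$age_F, s$age_R2, s$age_p))
  cat(sprintf("           variant: F = %.2f, R2 = %.3f, p = %.3g\n",
              s$variant_F, s$variant_R2, s$variant_p))
  cat(sprintf("  within vs between individual: %.3f vs %.3f, t = %.1f (df %.1f), p = %.3g\n",
              s$within_mean, s$between_mean, s$t_statistic, s$t_df, s$t_p))
  cat(sprintf("  NMDS stress = %.3f\n", s$nmds_stress))
  invisible(x)
}
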