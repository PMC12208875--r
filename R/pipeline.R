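#' Default pipeline configuration
#'
#' Nested list controlling [run_pipeline()]. Sections:
#' `cohort` (either `source = "simulate"` with [cohort_config()] overrides,
#' or `source = "files"` with a `path` readable by [read_cohort()]),
#' `criteria` ([inclusion_criteria()] overrides), `labeling` (`window`,
#' `tolerance_days`, `followup_days`), `model` ([model_config()] overrides),
#' `synergy` (`top_k`, grid-rule parameters), `report` (`rdw_threshold`,
#' `hgb_threshold`), and a master `seed`.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(source = "simulate"),
    criteria = list(),
    labeling = list(window = c(183L, 274L), tolerance_days = 14L,
                    followup_days = 365L),
    model = list(),
    synergy = list(top_k = 10L, single_max_candidates = 50L,
                   pair_max_candidates = 20L, min_group_size = 10L,
                   clip = c(0.1, 0.9)),
    report = list(rdw_threshold = 17, hgb_threshold = 15.5)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path",
                             call. = FALSE)
  if (is.null(config$cohort))
    stop("invalid pipeline config: field 'cohort' is required", call. = FALSE)
  if (is.null(config$cohort$source))
    stop("invalid pipeline config: field 'cohort$source' is required", call. = FALSE)
  merged <- modifyList(default_pipeline_config(), config)
  merged
}

#' Run the full resistance-prediction pipeline
#'
#' Executes simulate (or load) -> inclusion funnel -> resistance labeling ->
#' feature derivation -> random-forest ranking -> pairwise synergy scan ->
#' report, writing all tables and a JSON run summary to `outdir`. Fully
#' reproducible given the configuration seed.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML/JSON file.
#' @param outdir output directory (created if needed); `NULL` writes nothing.
#' @param plots also write PNG figures (quadrant scatter, stratified
#'   Kaplan-Meier curves)?
#' @param quiet suppress per-stage log messages?
#' @return object of class `pv_report`: `cohort`, `funnel`, `labels`,
#'   `features`, `model` (a `hu_rf`), `synergy` (a `synergy_table`),
#'   `rdw_comparison`, `quadrants`, `summary` (the run summary written to
#'   `summary.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL,
                         plots = TRUE, quiet = FALSE) {
  cfg <- read_pipeline_config(config)
  say <- function(...) if (!quiet) message("[pvresist] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## ---- simulate / load ----
  cohort <- stage("simulate", {
    if (identical(cfg$cohort$source, "simulate")) {
      gen_args <- cfg$cohort[setdiff(names(cfg$cohort), "source")]
      if (is.null(gen_args$seed)) gen_args$seed <- cfg$seed
      coh <- do.call(cohort_config, gen_args)
      say("simulating cohort: n = %d, seed = %d", coh$n_patients, coh$seed)
      generate_cohort(coh)
    } else if (identical(cfg$cohort$source, "files")) {
      if (is.null(cfg$cohort$path))
        stop("cohort$source = 'files' requires field 'cohort$path'")
      say("reading cohort from %s", cfg$cohort$path)
      read_cohort(cfg$cohort$path)
    } else stop("cohort$source must be 'simulate' or 'files'")
  })

  ## ---- inclusion funnel ----
  sel <- stage("select", {
    crit <- do.call(inclusion_criteria, cfg$criteria)
    apply_inclusion_funnel(cohort$patients, cohort$events, crit)
  })
  say("funnel: %d of %d patients retained",
      nrow(sel$patients), nrow(cohort$patients))

  ## ---- labeling + features ----
  lab <- stage("label", {
    label_cohort(sel$events, sel$patients$patient_id,
                 window = cfg$labeling$window,
                 tolerance_days = cfg$labeling$tolerance_days,
                 followup_days = cfg$labeling$followup_days)
  })
  say("labeled: %d resistant / %d non-resistant",
      sum(lab$resistant), sum(!lab$resistant))
  features <- stage("label", derive_feature_table(sel$patients, sel$events))

  ## ---- random forest ----
  model <- stage("train", {
    margs <- cfg$model
    if (is.null(margs$seed)) margs$seed <- cfg$seed + 1L
    fit_resistance_model(features, lab$resistant, do.call(model_config, margs))
  })
  say("composite CV ROC-AUC %.3f (validation %.3f)",
      model$cv$composite_auc, model$validation_auc)

  ## ---- pairwise synergy on the top ten variables ----
  synergy <- stage("synergy", {
    top <- head(model$cv$ranking$feature, cfg$synergy$top_k)
    surv <- data.frame(time = lab$event_day, event = lab$resistant)
    x <- as.data.frame(as_feature_matrix(features))
    rank_pairs(x, surv, features = top,
               single_rule = split_grid_rule(cfg$synergy$clip,
                                             cfg$synergy$single_max_candidates,
                                             cfg$synergy$min_group_size),
               pair_rule = split_grid_rule(cfg$synergy$clip,
                                           cfg$synergy$pair_max_candidates,
                                           cfg$synergy$min_group_size))
  })
  say("top synergy pair: %s-%s (S = %.3g)",
      synergy$var1[1], synergy$var2[1], synergy$synergy[1])

  ## ---- report ----
  rep <- stage("report", {
    rule <- risk_rule(cfg$report$rdw_threshold, cfg$report$hgb_threshold)
    quad <- classify_quadrant(features$RDW, features$HGB, rule)
    quad_tab <- quadrant_enrichment(features$RDW, features$HGB,
                                    rule$rdw_threshold, rule$hgb_threshold,
                                    lab$resistant)
    cmp <- compare_groups(features, lab$resistant, "RDW", rule$rdw_threshold)
    list(rule = rule, quadrant = quad, quadrant_table = quad_tab,
         rdw_comparison = cmp)
  })

  summary <- list(
    seed = cfg$seed,
    n_simulated = nrow(cohort$patients),
    funnel = sel$report,
    n_resistant = sum(lab$resistant),
    n_non_resistant = sum(!lab$resistant),
    composite_auc = model$cv$composite_auc,
    per_fold_auc = model$cv$per_fold_auc,
    validation_auc = model$validation_auc,
    top10 = model$top10[, c("feature", "rank_score", "direction")],
    top_pair = as.data.frame(synergy)[1, c("var1", "var2", "p1", "p2",
                                           "expected_p", "p12", "synergy",
                                           "t1", "t2", "quadrant")],
    quadrants = rep$quadrant_table,
    rdw_group_ratio = rep$rdw_comparison$proportion_ratio,
    rdw_group_p = rep$rdw_comparison$proportion_p,
    n_logrank_tests = attr(synergy, "n_tests")
  )

  out <- structure(list(cohort = cohort, funnel = sel$report, labels = lab,
                        features = features, model = model, synergy = synergy,
                        rdw_comparison = rep$rdw_comparison,
                        quadrant = rep$quadrant,
                        quadrants = rep$quadrant_table, rule = rep$rule,
                        summary = summary, config = cfg),
                   class = "pv_report")

  if (!is.null(outdir)) {
    stage("report", write_report_bundle(out, outdir, plots = plots))
    say("report written to %s", outdir)
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_report_bundle <- function(report, outdir, plots = TRUE) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (identical(report$config$cohort$source, "simulate"))
    write_cohort(report$cohort, outdir)
  write_tsv(report$funnel, file.path(outdir, "funnel.tsv"))
  feat <- report$features
  feat$resistant <- report$labels$resistant
  feat$event_day <- report$labels$event_day
  write.csv(feat, file.path(outdir, "features.csv"), row.names = FALSE)
  rk <- report$model$cv$ranking
  rk$rank <- seq_len(nrow(rk))
  write_tsv(rk[, c("rank", "feature", "rank_score", "direction")],
            file.path(outdir, "ranking.tsv"))
  jsonlite::write_json(
    list(composite_auc = report$model$cv$composite_auc,
         per_fold_auc = report$model$cv$per_fold_auc,
         validation_auc = report$model$validation_auc,
         config = report$model$config[c("train_fraction", "n_folds", "n_trees",
                                        "min_leaf", "importance_method", "seed")]),
    file.path(outdir, "eval.json"), auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write_tsv(as.data.frame(report$synergy), file.path(outdir, "pairs.tsv"))
  write_tsv(attr(report$synergy, "associations"),
            file.path(outdir, "associations.tsv"))
  jsonlite::write_json(report$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  if (plots) {
    grDevices::png(file.path(outdir, "rdw_hgb_scatter.png"), 700, 600)
    plot_quadrant_scatter(report$features$RDW, report$features$HGB,
                          report$labels$resistant, report$rule)
    grDevices::dev.off()
    grDevices::png(file.path(outdir, "km_quadrants.png"), 700, 600)
    plot_km_strata(data.frame(time = report$labels$event_day,
                              event = report$labels$resistant),
                   report$quadrant$quadrant)
    grDevices::dev.off()
  }
  invisible(outdir)
}

#' @export
print.pv_report <- function(x, ...) {
  cat("Hydroxyurea-resistance analysis report\n")
  print(x$funnel)
  cat(sprintf("Labeled resistant: %d / %d\n", sum(x$labels$resistant),
              nrow(x$labels)))
  cat(sprintf("Composite CV ROC-AUC: %.3f (validation %.3f)\n",
              x$model$cv$composite_auc, x$model$validation_auc))
  cat(sprintf("Top synergy pair: %s-%s, S = %.3g at (%g, %g)\n",
              x$synergy$var1[1], x$synergy$var2[1], x$synergy$synergy[1],
              x$synergy$t1[1], x$synergy$t2[1]))
  invisible(x)
}
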