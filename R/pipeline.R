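#' Configuration for a full pipeline run
#'
#' Defaults reproduce the study settings where stated: 40% training split,
#' the six-point Lasso penalty grid, residual-mode age-bias correction,
#' K swept from 2 to 5 with five-fold cross-validated stability, Bonferroni
#' q < 0.01 on the IDPs, and p < 0.05 contrasts elsewhere.
#'
#' @param generator a [generator_config()] (ignored when `cohort_path` points
#'   at an existing cohort file).
#' @param output_dir directory for all artifacts (created if needed).
#' @param cohort_path optional path to a user-supplied cohort CSV/TSV.
#' @param schema schema for a user-supplied cohort (default [ukb_schema()]).
#' @param train_fraction training fraction (default 0.40).
#' @param alpha_grid Lasso penalty grid.
#' @param correction_mode BrainAGE correction mode (default `"residual"`).
#' @param k_range candidate subtype counts (default 2:5).
#' @param n_folds stability CV folds (default 5).
#' @param n_init fused initializations per HYDRA fit (default 10).
#' @param C margin/loss trade-off (default 0.01 on the standardized
#'   residual scale).
#' @param q_threshold Bonferroni family threshold (default 0.01).
#' @param alpha_level contrast significance level (default 0.05).
#' @param cluster_targets `"stratified"` clusters the stratified ABA group
#'   against stratified RBA; `"truth"` uses planted ground-truth flags
#'   (synthetic cohorts only).
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator, output_dir,
                       cohort_path = NULL, schema = NULL,
                       train_fraction = 0.40,
                       alpha_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                       correction_mode = "residual",
                       k_range = 2:5, n_folds = 5L, n_init = 10L, C = 0.01,
                       q_threshold = 0.01, alpha_level = 0.05,
                       cluster_targets = c("stratified", "truth"),
                       seed = 1L) {
  cluster_targets <- match.arg(cluster_targets)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("config_error", "train_fraction must lie in (0, 1)")
  }
  structure(list(generator = generator, output_dir = output_dir,
                 cohort_path = cohort_path, schema = schema,
                 train_fraction = train_fraction, alpha_grid = alpha_grid,
                 correction_mode = correction_mode, k_range = k_range,
                 n_folds = as.integer(n_folds), n_init = as.integer(n_init),
                 C = C, q_threshold = q_threshold, alpha_level = alpha_level,
                 cluster_targets = cluster_targets, seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, code) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(code), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  stage_log(stage, "done in %.1fs", proc.time()[["elapsed"]] - t0)
  out
}

#' Run the full subtyping pipeline
#'
#' Executes simulate (or load) -> split -> brain-age models -> stratify ->
#' cluster -> characterize, persisting every intermediate artifact under
#' `config$output_dir` together with a machine-readable `manifest.json`
#' (configuration, per-stage row counts, artifact checksums). Two runs with
#' the same configuration and seed produce file-identical artifacts; stage
#' durations go to standard error only.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  artifacts <- character(0)
  stages <- list()
  seed <- config$seed

  # --- stage 1: cohort --------------------------------------------------
  cohort <- run_stage("simulate", {
    if (!is.null(config$cohort_path)) {
      schema <- if (is.null(config$schema)) ukb_schema() else config$schema
      co <- read_cohort(config$cohort_path, schema)
      stage_log("simulate", "loaded %d subjects from %s", n_subjects(co),
                config$cohort_path)
      co
    } else {
      gen <- config$generator
      gen$seed <- derive_seed(seed, 10L)
      sim <- generate_cohort(gen)
      co <- sim$cohort
      write_cohort(co, out("cohort.csv"))
      truth_df <- data.frame(subject_id = names(sim$truth$aba_flag),
                             aba_flag = as.integer(sim$truth$aba_flag),
                             subtype_label = sim$truth$subtype_label,
                             severity = sim$truth$severity,
                             delta = sim$truth$delta,
                             stringsAsFactors = FALSE)
      write_table_precise(truth_df, out("ground_truth.csv"))
      stage_log("simulate", "generated %d subjects, %d IDPs", n_subjects(co),
                length(idp_columns(co$schema)))
      co
    }
  })
  cfg_serializable <- config
  cfg_serializable$schema <- NULL
  # the output directory is implied by the artifact location; keeping it out
  # of the serialized config makes runs file-identical wherever they land
  cfg_serializable$output_dir <- NULL
  cfg_serializable$generator <- unclass(config$generator)
  jsonlite::write_json(unclass(cfg_serializable), out("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, "config.json",
                 if (is.null(config$cohort_path)) c("cohort.csv", "ground_truth.csv"))
  stages$simulate <- list(n_subjects = n_subjects(cohort))

  # --- stage 2: split + brain-age models -------------------------------
  split <- run_stage("split", {
    sp <- split_cohort(cohort, config$train_fraction, seed = derive_seed(seed, 20L))
    ids <- data.frame(subject_id = subject_ids(cohort),
                      set = ifelse(subject_ids(cohort) %in% subject_ids(sp$train),
                                   "train", "test"),
                      stringsAsFactors = FALSE)
    write_table_precise(ids, out("split.csv"))
    stage_log("split", "%d train / %d test", n_subjects(sp$train),
              n_subjects(sp$test))
    sp
  })
  artifacts <- c(artifacts, "split.csv")
  stages$split <- list(n_train = n_subjects(split$train),
                       n_test = n_subjects(split$test))

  modalities <- names(cohort$schema$modality_blocks)
  predictions <- list()
  mae <- numeric(0)
  run_stage("brainage", {
    for (m in modalities) {
      fit <- fit_brainage(split$train, m, alpha_grid = config$alpha_grid,
                          seed = derive_seed(seed, 30L),
                          correction_mode = config$correction_mode)
      pred <- predict(fit, split$test)
      predictions[[m]] <- pred
      mae[m] <- evaluate_mae(pred$predicted_raw, pred$age)
      write_brainage_model(fit, out(sprintf("brainage_model_%s.json", m)))
      write_table_precise(pred, out(sprintf("predictions_%s.csv", m)))
      stage_log("brainage", "%s: penalty %g, test MAE %.2f y", m, fit$penalty,
                mae[m])
    }
    NULL
  })
  artifacts <- c(artifacts, sprintf("brainage_model_%s.json", modalities),
                 sprintf("predictions_%s.csv", modalities))
  stages$brainage <- list(test_mae = as.list(mae))

  # --- stage 3: stratification ------------------------------------------
  strat <- run_stage("stratify", {
    ba <- lapply(predictions, function(p) stats::setNames(p$brainage, p$subject_id))
    s <- stratify(ba[[1]], ba[[2]], ba[[3]])
    write_table_precise(as.data.frame(s), out("stratification.csv"))
    counts <- stratification_summary(s)
    jsonlite::write_json(as.list(counts), out("stratification_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_log("stratify", "ABA %d / RBA %d / MIXED %d", counts[["ABA"]],
              counts[["RBA"]], counts[["MIXED"]])
    s
  })
  artifacts <- c(artifacts, "stratification.csv", "stratification_summary.json")
  stages$stratify <- as.list(stratification_summary(strat))

  # --- stage 4: clustering ----------------------------------------------
  cluster <- run_stage("cluster", {
    test <- split$test
    ids <- subject_ids(test)
    if (config$cluster_targets == "truth") {
      if (is.null(test$truth)) {
        stopf("config_error", "truth targets requested but cohort has no ground truth")
      }
      is_target <- unname(test$truth$aba_flag[ids])
      in_scope <- rep(TRUE, length(ids))
    } else {
      grp <- strat$group[match(ids, strat$subject_id)]
      in_scope <- grp %in% c("ABA", "RBA")
      is_target <- grp == "ABA"
    }
    rows <- which(in_scope)
    if (!sum(is_target[rows]) || all(is_target[rows])) {
      stopf("config_error", "need nonempty target and control groups to cluster")
    }
    x <- as.matrix(test$data[rows, idp_columns(test$schema), drop = FALSE])
    covs <- cbind(age = test$data[[test$schema$age_column]][rows],
                  sex = test$data[[test$schema$sex_column]][rows],
                  education = test$data[[test$schema$education_column]][rows])
    res <- residualize_covariates(x, covs, reference_mask = !is_target[rows])
    curve <- cluster_stability(res, is_target[rows], k_range = config$k_range,
                               n_folds = config$n_folds, n_init = config$n_init,
                               C = config$C, seed = derive_seed(seed, 40L))
    fit <- hydra(res, is_target[rows], K = curve$selected_k, C = config$C,
                 n_init = config$n_init, seed = derive_seed(seed, 41L))
    write_table_precise(data.frame(K = curve$k_values, mean_ari = curve$mean_ari),
                        out("stability_curve.csv"))
    target_ids <- ids[rows][is_target[rows]]
    write_table_precise(data.frame(subject_id = target_ids,
                                   subtype = fit$assignments,
                                   stringsAsFactors = FALSE),
                        out("subtype_labels.csv"))
    jsonlite::write_json(list(K = fit$K,
                              hyperplane_weights = unname(fit$model$hyperplane_weights),
                              hyperplane_offsets = fit$model$hyperplane_offsets,
                              objective_trace = fit$model$objective_trace,
                              converged = fit$model$converged),
                         out("polytope_model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_log("cluster", "selected K = %d (stability %s)", curve$selected_k,
              paste(sprintf("%d:%.2f", curve$k_values, curve$mean_ari),
                    collapse = " "))
    list(curve = curve, fit = fit, rows = rows, is_target = is_target,
         target_ids = target_ids)
  })
  artifacts <- c(artifacts, "stability_curve.csv", "subtype_labels.csv",
                 "polytope_model.json")
  stages$cluster <- list(selected_k = cluster$curve$selected_k,
                         mean_ari = as.list(stats::setNames(
                           cluster$curve$mean_ari,
                           paste0("K", cluster$curve$k_values))),
                         n_targets = length(cluster$target_ids))

  # --- stage 5: characterization ----------------------------------------
  report <- run_stage("characterize", {
    test <- split$test
    ids <- subject_ids(test)
    groups <- rep(NA_character_, length(ids))
    rows <- cluster$rows
    groups[rows][!cluster$is_target[rows]] <- "RBA"
    groups[match(cluster$target_ids, ids)] <-
      sprintf("SubGroup%d", cluster$fit$assignments)
    rep <- characterize_subtypes(test, stats::setNames(groups, ids),
                                 reference = "RBA",
                                 q_threshold = config$q_threshold,
                                 alpha = config$alpha_level)
    write_table_precise(merge(rep$idp, rep$zscores, by = "idp", sort = FALSE),
                        out("report_idps.csv"))
    write_table_precise(as.data.frame(rep$cognitive), out("report_cognitive.csv"))
    write_table_precise(as.data.frame(rep$qualitative), out("report_qualitative.csv"))
    stage_log("characterize", "%d IDPs flagged at q < %g",
              sum(rep$idp$significant), config$q_threshold)
    rep
  })
  artifacts <- c(artifacts, "report_idps.csv", "report_cognitive.csv",
                 "report_qualitative.csv")
  stages$characterize <- list(n_flagged_idps = sum(report$idp$significant),
                              groups = as.list(table(report$groups)))

  manifest <- list(package = "abasubtypes",
                   version = as.character(utils::packageVersion("abasubtypes")),
                   seed = seed,
                   config = unclass(cfg_serializable),
                   stages = stages,
                   artifacts = lapply(stats::setNames(artifacts, artifacts),
                                      function(f) {
                                        list(md5 = unname(tools::md5sum(out(f))))
                                      }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
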