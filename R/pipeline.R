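#' Run the full driver-discovery pipeline on one cohort
#'
#' The five-step outline: (1) mask and scale features; (2) fit the BMR model
#' on the training elements — either gradient-boosted Poisson trees on the
#' imputed feature matrix, or randomised-lasso feature selection followed by
#' a binomial GLM on robust-scaled features — and predict expected counts
#' for the test elements; (3) burden-test balanced counts with BH
#' correction, dispatching to a negative-binomial null when the
#' overdispersion test on the training set rejects; (4) adjust the counts of
#' nearly significant elements (cohort q < `cfg$q_gate`) by the functional
#' weight; (5) re-test and report cohort and global q-values.
#'
#' @param elements test `element_set` (already masked)
#' @param training neutral training `element_set` (already masked)
#' @param mutations mutation table (see [read_mutations()])
#' @param X feature matrix over test elements (raw/unscaled; imputation and
#'   any scaling are handled internally per model)
#' @param X_train feature matrix over training elements
#' @param model "gbm" (default) or "glm"
#' @param raw_scores optional per-mutation raw functional scores
#'   (`chrom pos0 ref alt scheme raw_score`); NULL skips the functional
#'   adjustment (all weights 1)
#' @param donors optional cohort roster (character); defaults to donors seen
#'   in `mutations`
#' @param lymphoma logical; lymphoid cohorts use dispersion scaling s = 3
#'   (s = 1 otherwise). Never inferred from data.
#' @param cfg an [adjustment_config()]
#' @param seed root seed; model fitting and feature selection derive their
#'   streams from it
#' @param gbm_config a [gbm_params()] (gbm model only)
#' @param rlasso pass-through arguments for [select_features_rlasso()]
#'   (glm model only), e.g. `list(n_repeats = 100)`
#' @param cohort cohort label echoed in the results
#' @param set_name element-set label echoed in the results
#' @return list of class `driverscan_run`: `results` (the significance
#'   table), `prediction`, `dispersion`, `model`, `selection` (glm only),
#'   `evaluation` of the training fit, and `manifest` (config echo, seeds,
#'   counts, package version)
#' @export
infer_drivers <- function(elements, training, mutations, X, X_train,
                          model = c("gbm", "glm"), raw_scores = NULL,
                          donors = NULL, lymphoma = FALSE,
                          cfg = adjustment_config(), seed = 1,
                          gbm_config = gbm_params(), rlasso = list(),
                          cohort = "cohort1", set_name = "elements") {
  model <- match.arg(model)
  mutations <- data.table::as.data.table(mutations)
  if (is.null(donors)) donors <- sort(unique(mutations$donor_id))
  # test and training sets live on different chromosome subsets; count each
  # against the mutations on its own chromosomes
  chr_test <- as.character(unique(GenomicRanges::seqnames(elements$gr)))
  chr_train <- as.character(unique(GenomicRanges::seqnames(training$gr)))
  cat_test <- count_mutations(mutations[chrom %in% chr_test], elements,
                              donors = donors)
  cat_train <- count_mutations(mutations[chrom %in% chr_train], training,
                               donors = donors)
  sel <- NULL
  Xtr <- as.matrix(X_train)[.catalog_table(cat_train)$element_id, , drop = FALSE]
  Xte <- as.matrix(X)[.catalog_table(cat_test)$element_id, , drop = FALSE]
  if (model == "gbm") {
    Xtr[is.na(Xtr)] <- 0
    Xte[is.na(Xte)] <- 0
    fit <- fit_bmr_gbm(Xtr, cat_train, config = gbm_config, seed = seed)
    pred_train <- predict_expected(fit, Xtr, cat_train)
    pred_test <- predict_expected(fit, Xte, cat_test)
  } else {
    sc_train <- impute_and_scale(Xtr)
    sc_test <- impute_and_scale(Xte, sc_train$stats)
    sel <- do.call(select_features_rlasso,
                   c(list(X = sc_train$X, catalog = cat_train, seed = seed),
                     rlasso))
    keep <- sel$selected
    fit <- fit_bmr_glm(sc_train$X[, keep, drop = FALSE], cat_train)
    pred_train <- predict_expected(fit, sc_train$X[, keep, drop = FALSE], cat_train)
    pred_test <- predict_expected(fit, sc_test$X[, keep, drop = FALSE], cat_test)
  }
  disp <- test_overdispersion(.catalog_table(cat_train)$y, pred_train$yhat,
                              s = if (lymphoma) 3 else 1)
  impacts <- if (!is.null(raw_scores) && nrow(raw_scores)) {
    functional_impact(cat_test, raw_scores, F = cfg$F, mutations = mutations)
  } else NULL
  results <- run_significance(cat_test, pred_test, disp = disp,
                              impacts = impacts, cfg = cfg,
                              set_name = set_name, cohort = cohort)
  manifest <- list(
    package = "driverscan",
    version = as.character(utils::packageVersion("driverscan")),
    model = model, seed = seed, lymphoma = lymphoma,
    config = unclass(cfg),
    n_test_elements = nrow(cat_test$counts),
    n_train_elements = nrow(cat_train$counts),
    n_donors = cat_test$N,
    n_mutations = nrow(mutations),
    dispersion = list(theta = disp$theta, p_od = disp$p_od, s = disp$s),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(list(results = results, prediction = pred_test,
                 dispersion = disp, model = fit, selection = sel,
                 manifest = manifest),
            class = "driverscan_run")
}

#' @export
print.driverscan_run <- function(x, ...) {
  ns <- sum(x$results$flag == "significant", na.rm = TRUE)
  cat(sprintf("driverscan_run (%s): %d elements tested, %d significant (global q < %.2g); theta = %.3g (p_od = %.2g)\n",
              x$manifest$model, sum(x$results$flag != "untestable"), ns,
              x$manifest$config$q_sig, x$dispersion$theta, x$dispersion$p_od))
  invisible(x)
}

#' Write the run manifest alongside the results
#' @param run a `driverscan_run`
#' @param dir output directory
#' @return dir, invisibly
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results_tsv(run$results, file.path(dir, "results.tsv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
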