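#' @title Background mutation rate (BMR) models
#'
#' @description The burden test compares each element's observed count y to
#' the count expected under neutrality, yhat = E(y | X, L), learned on
#' neutral training elements. Two BMR models are provided: a binomial GLM on
#' features retained by randomised-lasso stability selection, and gradient
#' boosted trees with a Poisson objective and log(N*L) offset.
#'
#' @name bmr
NULL

# logit-transformed per-base per-donor rate used as the lasso response
.lasso_response <- function(y, N, L) qlogis((y + 0.5) / (N * L))

#' Stability selection of BMR features with a randomised lasso
#'
#' The regularisation strength alpha is fixed once by a 5-fold
#' cross-validated lasso on a random `cv_frac` subset of the training rows
#' (1-SE rule).
#' Then, `n_repeats` times, a fresh `subsample_frac` subsample is drawn and an
#' L1-penalised least-squares fit of the logit-transformed mutation rate,
#' logit((y + 1/2) / (N * L)), is run with per-feature penalty alpha / b_i,
#' where the random weaknesses b_i are i.i.d. uniform on [0.5, 1] per repeat.
#' A feature counts as selected in a repeat when its coefficient magnitude
#' reaches `select_cut`. The importance score is the fraction of repeats in
#' which a feature was selected; features with importance above
#' `keep_threshold` feed the GLM.
#'
#' @param X scaled feature matrix over training elements
#' @param catalog a `mutation_catalog` for the same elements (row order of
#'   `X` must match `catalog$counts`, testable elements only)
#' @param n_repeats subsample repeats (default 500)
#' @param subsample_frac fraction of rows per repeat (default 0.10)
#' @param select_cut coefficient magnitude counting as selected (default 1e-3)
#' @param keep_threshold importance needed to keep a feature (default 0.5)
#' @param cv_frac fraction of rows used for the CV-lasso alpha search
#'   (default 0.33)
#' @param seed integer seed (CV and subsampling use independent streams)
#' @return object of class `lasso_selection` with `alpha`, `importance`,
#'   `selected`
#' @export
select_features_rlasso <- function(X, catalog, n_repeats = 500,
                                   subsample_frac = 0.10, select_cut = 1e-3,
                                   keep_threshold = 0.5, cv_frac = 0.33,
                                   seed = 1) {
  X <- as.matrix(X)
  ct <- .catalog_table(catalog)
  stopifnot(nrow(X) == nrow(ct))
  if (nrow(X) < 10) stop("need at least 10 training rows for feature selection")
  r <- .lasso_response(ct$y, catalog$N, ct$L)
  p <- ncol(X)
  if (var(r) == 0) {
    # constant response: the lasso shrinks every coefficient to zero
    return(structure(list(alpha = Inf,
                          importance = setNames(rep(0, p), colnames(X)),
                          selected = character(0), n_repeats = n_repeats,
                          subsample_frac = subsample_frac,
                          select_cut = select_cut,
                          keep_threshold = keep_threshold, seed = seed),
                     class = "lasso_selection"))
  }

  alpha <- withr::with_seed(seed, {
    idx <- sample.int(nrow(X), max(20, ceiling(cv_frac * nrow(X))))
    cvfit <- glmnet::cv.glmnet(X[idx, , drop = FALSE], r[idx], nfolds = 5,
                               standardize = FALSE, intercept = TRUE)
    # glmnet minimises RSS/(2n) + lambda*|w|_1; the selection objective uses
    # RSS/n, so alpha = 2 * lambda on that scale. The 1-SE lambda is used:
    # the CV curve is flat near its minimum, and under a pure-noise response
    # the minimum-CV lambda is unstable enough to let noise features through
    # stability selection; the 1-SE choice keeps the selector conservative.
    2 * cvfit$lambda.1se
  })

  n_sub <- max(2, ceiling(subsample_frac * nrow(X)))
  hits <- withr::with_seed(seed + 1L, {
    h <- numeric(p)
    for (k in seq_len(n_repeats)) {
      idx <- sample.int(nrow(X), n_sub)
      b <- runif(p, 0.5, 1)
      pf <- 1 / b
      # glmnet rescales penalty.factor to sum to nvars; undo so the
      # effective per-feature penalty is (alpha/2)/b_i
      lam <- (alpha / 2) * mean(pf)
      fit <- glmnet::glmnet(X[idx, , drop = FALSE], r[idx], lambda = lam,
                            penalty.factor = pf, standardize = FALSE,
                            intercept = TRUE)
      w <- as.numeric(fit$beta)
      h <- h + (abs(w) >= select_cut)
    }
    h
  })
  importance <- setNames(hits / n_repeats, colnames(X))
  structure(list(alpha = alpha, importance = importance,
                 selected = names(importance)[importance > keep_threshold],
                 n_repeats = n_repeats, subsample_frac = subsample_frac,
                 select_cut = select_cut, keep_threshold = keep_threshold,
                 seed = seed),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("lasso_selection: alpha = %.4g, %d/%d features selected (importance > %.2f)\n",
              x$alpha, length(x$selected), length(x$importance), x$keep_threshold))
  invisible(x)
}

#' Fit the binomial GLM BMR model
#'
#' Observed counts are modelled as y ~ Binomial(n, p) with n = N * L trials
#' and p the per-base per-donor mutation probability, linked to the selected
#' features by logit(p) = X beta. The fit works on rates with binomial
#' weights, so n up to 1e10 is handled without expanding trials.
#'
#' @param X scaled feature matrix over training elements (selected features
#'   only; may have zero columns for an intercept-only model)
#' @param catalog `mutation_catalog` aligned with the rows of `X`
#' @return object of class `bmr_glm` with coefficients, standard errors and
#'   the feature schema
#' @export
fit_bmr_glm <- function(X, catalog) {
  X <- as.matrix(X)
  ct <- .catalog_table(catalog)
  stopifnot(nrow(X) == nrow(ct))
  n <- round(catalog$N * ct$L)
  if (any(ct$y > n)) stop("observed count exceeds N * L trials")
  if (all(ct$y == 0)) warning("all observed counts are zero; rate fit is at the boundary")
  df <- data.frame(rate = ct$y / n)
  form <- if (ncol(X) > 0) {
    colnames(X) <- make.names(colnames(X))
    df <- cbind(df, as.data.frame(X))
    stats::reformulate(colnames(X), response = "rate")
  } else rate ~ 1
  fit <- suppressWarnings(glm(form, family = binomial("logit"), weights = n, data = df))
  if (!fit$converged) stop("binomial GLM did not converge after ", fit$iter, " iterations")
  sm <- summary(fit)
  structure(list(beta = coef(fit), se = sm$coefficients[, "Std. Error"],
                 feature_names = colnames(X), converged = fit$converged),
            class = "bmr_glm")
}

#' @export
print.bmr_glm <- function(x, ...) {
  cat(sprintf("bmr_glm: logit-link binomial model, %d features + intercept\n",
              length(x$feature_names)))
  invisible(x)
}

#' Default configuration for the gradient-boosted BMR model
#'
#' @param eta learning rate (default 0.05)
#' @param max_depth maximum tree depth (default 8)
#' @param subsample row subsample per round (default 0.6)
#' @param max_delta_step Poisson stabilisation (default 1.2)
#' @param early_stop_rounds stop after this many non-improving rounds
#'   (default 5)
#' @param nrounds maximum boosting rounds (default 5000)
#' @param valid_frac fraction of training rows held out for early stopping
#'   (default 0.2)
#' @return list of class `gbm_config`
#' @export
gbm_params <- function(eta = 0.05, max_depth = 8, subsample = 0.6,
                       max_delta_step = 1.2, early_stop_rounds = 5,
                       nrounds = 5000, valid_frac = 0.2) {
  structure(list(eta = eta, max_depth = max_depth, subsample = subsample,
                 max_delta_step = max_delta_step,
                 early_stop_rounds = early_stop_rounds, nrounds = nrounds,
                 valid_frac = valid_frac), class = "gbm_config")
}

#' Fit the gradient-boosted BMR model
#'
#' Boosted regression trees minimising the negative Poisson log-likelihood of
#' y against exp(log(N * L) + f(x)); the log-exposure offset makes the trees
#' model the per-base per-donor rate. A random `valid_frac` of the training
#' rows is held out and training stops once the validation deviance fails to
#' improve for `early_stop_rounds` rounds. All features are used (unscaled,
#' imputed).
#'
#' @param X imputed (unscaled) feature matrix over training elements
#' @param catalog `mutation_catalog` aligned with the rows of `X`
#' @param config a `gbm_params()` list
#' @param seed integer seed (validation split and tree subsampling)
#' @return object of class `bmr_gbm`
#' @export
fit_bmr_gbm <- function(X, catalog, config = gbm_params(), seed = 1) {
  X <- as.matrix(X)
  ct <- .catalog_table(catalog)
  stopifnot(nrow(X) == nrow(ct))
  if (all(ct$y == 0)) warning("all observed counts are zero; GBM will predict ~0")
  offset <- log(catalog$N * ct$L)
  withr::with_seed(seed, {
    val <- sample.int(nrow(X), max(1, floor(config$valid_frac * nrow(X))))
    dtr <- xgboost::xgb.DMatrix(X[-val, , drop = FALSE], label = ct$y[-val],
                                base_margin = offset[-val], nthread = 1)
    dva <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = ct$y[val],
                                base_margin = offset[val], nthread = 1)
    booster <- xgboost::xgb.train(
      params = xgboost::xgb.params(
        objective = "count:poisson", learning_rate = config$eta,
        max_depth = config$max_depth, subsample = config$subsample,
        max_delta_step = config$max_delta_step, nthread = 1, seed = seed),
      data = dtr, nrounds = config$nrounds, evals = list(valid = dva),
      early_stopping_rounds = config$early_stop_rounds, verbose = 0)
    structure(list(booster = booster, feature_names = colnames(X),
                   config = config, seed = seed,
                   best_iteration = xgboost::xgb.attr(booster, "best_iteration")),
              class = "bmr_gbm")
  })
}

#' @export
print.bmr_gbm <- function(x, ...) {
  cat(sprintf("bmr_gbm: Poisson-objective boosted trees, %d features, best iteration %s\n",
              length(x$feature_names), x$best_iteration))
  invisible(x)
}

#' Normalised feature importance of the GBM
#'
#' Gain-based importance (improvement in the objective brought by each
#' feature across all trees). Raw gains sum to 1 over used features; the
#' normalised score rescales so the most important feature is exactly 1.
#' Features never used get 0.
#'
#' @param model a `bmr_gbm`
#' @return data.table with `feature`, `gain`, `normalized`
#' @export
gbm_importance <- function(model) {
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- data.table::data.table(feature = model$feature_names, gain = 0)
  out[match(imp$Feature, feature), gain := imp$Gain]
  out[, gain := gain / sum(gain)]
  out[, normalized := gain / max(gain)]
  out[]
}

#' Expected mutation counts for an element set
#'
#' @param model a fitted `bmr_glm` or `bmr_gbm`
#' @param X feature matrix for the elements to predict, with columns matching
#'   the model's training schema (scaled for the GLM, unscaled for the GBM)
#' @param catalog `mutation_catalog` providing N and per-element L aligned
#'   with the rows of `X` (testable elements)
#' @return data.table `element_id`, `L`, `yhat`; yhat > 0 for every element
#'   with positive effective length
#' @export
predict_expected <- function(model, X, catalog) UseMethod("predict_expected")

#' @export
predict_expected.bmr_glm <- function(model, X, catalog) {
  X <- as.matrix(X)
  ct <- .catalog_table(catalog)
  stopifnot(nrow(X) == nrow(ct))
  if (!identical(make.names(colnames(X)), make.names(model$feature_names))) {
    stop("feature schema mismatch between X and the fitted GLM")
  }
  eta <- model$beta[1] + if (ncol(X) > 0) {
    drop(X %*% model$beta[-1])
  } else 0
  data.table::data.table(element_id = ct$element_id, L = ct$L,
                         yhat = catalog$N * ct$L * plogis(eta))
}

#' @export
predict_expected.bmr_gbm <- function(model, X, catalog) {
  X <- as.matrix(X)
  ct <- .catalog_table(catalog)
  stopifnot(nrow(X) == nrow(ct))
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature schema mismatch between X and the fitted GBM")
  }
  dm <- xgboost::xgb.DMatrix(X, base_margin = log(catalog$N * ct$L), nthread = 1)
  data.table::data.table(element_id = ct$element_id, L = ct$L,
                         yhat = as.numeric(predict(model$booster, dm)))
}

#' Cross-validated evaluation of a BMR model
#'
#' Standard mode trains on k-1 folds and evaluates on the held-out fold
#' (used for constant-width genome bins); inverted mode trains on one fold
#' and evaluates on the remaining k-1 (used for the large training-element
#' sets). Reports the R-squared score and Pearson's r of predicted vs
#' observed counts, with the standard error of the mean across folds.
#'
#' @param model_kind "glm" or "gbm"
#' @param X feature matrix (scaled for glm, unscaled-imputed for gbm)
#' @param catalog aligned `mutation_catalog`
#' @param k_folds number of folds (default 5)
#' @param mode "standard" or "inverted"
#' @param seed integer seed for the fold split
#' @param config optional `gbm_params()` for the gbm
#' @return list with `R2`, `pearson_r`, `sem_R2`, `sem_r`, `folds`
#' @export
evaluate_cv <- function(model_kind = c("glm", "gbm"), X, catalog, k_folds = 5,
                        mode = c("standard", "inverted"), seed = 1,
                        config = gbm_params()) {
  model_kind <- match.arg(model_kind)
  mode <- match.arg(mode)
  stopifnot(k_folds >= 2)
  X <- as.matrix(X)
  ct <- .catalog_table(catalog)
  stopifnot(nrow(X) == nrow(ct))
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k_folds), nrow(X))))
  r2s <- rs <- rep(NA_real_, k_folds)
  for (f in seq_len(k_folds)) {
    tr <- if (mode == "standard") folds != f else folds == f
    sub_cat_tr <- .subset_catalog(catalog, which(tr))
    sub_cat_te <- .subset_catalog(catalog, which(!tr))
    fit <- if (model_kind == "glm") {
      fit_bmr_glm(X[tr, , drop = FALSE], sub_cat_tr)
    } else {
      fit_bmr_gbm(X[tr, , drop = FALSE], sub_cat_tr, config = config,
                  seed = seed + f)
    }
    pred <- predict_expected(fit, X[!tr, , drop = FALSE], sub_cat_te)
    y <- sub_cat_te$counts$y
    if (var(y) == 0) next  # R2 undefined on a zero-variance fold
    m <- .cv_metrics(y, pred$yhat)
    r2s[f] <- m[["R2"]]
    rs[f] <- m[["r"]]
  }
  ok <- !is.na(r2s)
  list(R2 = mean(r2s[ok]), pearson_r = mean(rs[ok]),
       sem_R2 = sd(r2s[ok]) / sqrt(sum(ok)), sem_r = sd(rs[ok]) / sqrt(sum(ok)),
       folds = data.table::data.table(fold = seq_len(k_folds), R2 = r2s, r = rs))
}

#' Persist and restore fitted BMR models
#'
#' Versioned on-disk format embedding the feature schema, configuration and
#' seed alongside the fitted parameters; GBM boosters are stored through
#' xgboost's own serialisation so reloads predict identically.
#'
#' @param model a `bmr_glm` or `bmr_gbm`
#' @param path file path
#' @return `path` (save) or the restored model (load)
#' @export
save_bmr_model <- function(model, path) {
  obj <- list(format_version = 1L,
              package_version = as.character(utils::packageVersion("driverscan")),
              kind = class(model)[1])
  if (inherits(model, "bmr_gbm")) {
    obj$payload <- model[setdiff(names(model), "booster")]
    obj$booster_raw <- xgboost::xgb.save.raw(model$booster)
  } else {
    obj$payload <- unclass(model)
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_bmr_model
#' @export
load_bmr_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    stop("unknown model format version: ", obj$format_version)
  }
  model <- obj$payload
  if (obj$kind == "bmr_gbm") {
    model$booster <- xgboost::xgb.load.raw(obj$booster_raw)
  }
  class(model) <- obj$kind
  model
}

# internal: R-squared score and Pearson r of predicted vs observed counts
.cv_metrics <- function(y, yhat) {
  c(R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
    r = cor(y, yhat))
}

# internal: restrict a catalog to a row subset of its testable table
.subset_catalog <- function(catalog, rows) {
  ct <- .catalog_table(catalog)[rows]
  structure(list(counts = ct, N = catalog$N, donors = catalog$donors,
                 hits = NULL), class = "mutation_catalog")
}
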