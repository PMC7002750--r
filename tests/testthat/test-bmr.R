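# synthetic regression design shared by the model tests: element lengths,
# counts drawn from a known log-linear (GBM) or logit-linear (GLM) model
sim_design <- function(n, p, N = 200, seed = 1) {
  withr::with_seed(seed, {
    L <- pmax(100, round(stats::rlnorm(n, log(3000), 0.4)))
    X <- matrix(rnorm(n * p), n, p, dimnames = list(sprintf("e%05d", 1:n),
                                                    sprintf("f%02d", 1:p)))
    list(L = L, X = X, N = N)
  })
}

test_that("stability selection keeps an informative feature and drops noise", {
  d <- sim_design(2000, 11, seed = 2)
  eta <- qlogis(8e-6) + 0.8 * d$X[, 1]
  y <- withr::with_seed(3, rpois(2000, d$N * d$L * plogis(eta)))
  cat <- toy_catalog(y, d$L, d$N)
  Xs <- impute_and_scale(d$X)$X
  sel <- select_features_rlasso(Xs, cat, n_repeats = 100, seed = 9)
  expect_gt(sel$importance[["f01"]], 0.5)
  expect_lt(max(sel$importance[-1]), 0.5)
  expect_setequal(sel$selected, "f01")

  sel2 <- select_features_rlasso(Xs, cat, n_repeats = 100, seed = 9)
  expect_identical(sel2$importance, sel$importance)  # seeded determinism
})

test_that("a constant response selects nothing", {
  d <- sim_design(200, 5, seed = 4)
  cat <- toy_catalog(rep(3, 200), rep(1000, 200), d$N)
  sel <- select_features_rlasso(impute_and_scale(d$X[1:200, 1:5])$X, cat,
                                n_repeats = 20, seed = 1)
  expect_length(sel$selected, 0)
  expect_true(all(sel$importance == 0))
})

test_that("pure-noise features are rarely selected across seeds", {
  d <- sim_design(1500, 8, seed = 6)
  eta <- qlogis(8e-6) + withr::with_seed(7, 0.04 * rnorm(1500))  # noise, unrelated to X
  y <- withr::with_seed(8, rpois(1500, d$N * d$L * plogis(eta)))
  cat <- toy_catalog(y, d$L, d$N)
  Xs <- impute_and_scale(d$X)$X
  n_false <- 0L
  for (s in 1:10) {
    sel <- select_features_rlasso(Xs, cat, n_repeats = 60, seed = 100 + s)
    n_false <- n_false + length(sel$selected)
  }
  expect_lt(n_false / (10 * 8), 0.10)  # false-selection rate under 10%
})

test_that("intercept-only binomial GLM recovers the pooled rate exactly", {
  y <- c(3, 5, 0, 2)
  L <- c(1e4, 2e4, 5e3, 1e4)
  cat <- toy_catalog(y, L, N = 50)
  fit <- fit_bmr_glm(matrix(nrow = 4, ncol = 0), cat)
  expect_equal(unname(plogis(fit$beta[1])), sum(y) / sum(50 * L),
               tolerance = 1e-8)
  pred <- predict_expected(fit, matrix(nrow = 4, ncol = 0), cat)
  expect_equal(sum(pred$yhat), sum(y), tolerance = 1e-6)
})

test_that("binomial GLM recovers known coefficients within 3 SE", {
  ok <- 0L
  for (rep in 1:5) {
    d <- sim_design(3000, 2, seed = 20 + rep)
    beta <- c(qlogis(4e-6), 0.5, -0.3)
    eta <- beta[1] + drop(d$X %*% beta[-1])
    y <- withr::with_seed(30 + rep, rpois(3000, d$N * d$L * plogis(eta)))
    fit <- fit_bmr_glm(d$X, toy_catalog(y, d$L, d$N))
    ok <- ok + all(abs(fit$beta - beta) <= 3 * fit$se)
  }
  expect_gte(ok, 4)
})

test_that("degenerate all-zero counts hit the rate boundary with a warning", {
  cat <- toy_catalog(rep(0, 50), rep(1000, 50), N = 10)
  expect_warning(fit <- fit_bmr_glm(matrix(nrow = 50, ncol = 0), cat),
                 "boundary|zero")
  expect_lt(plogis(fit$beta[1]), 1e-6)
})

test_that("counts above N*L are rejected", {
  cat <- toy_catalog(y = 100, L = 1, N = 10)
  expect_error(fit_bmr_glm(matrix(nrow = 1, ncol = 0), cat), "exceeds")
})

test_that("GBM with an uninformative feature converges to the pooled rate", {
  d <- sim_design(2000, 1, seed = 40)
  rate <- 3e-6
  y <- withr::with_seed(41, rpois(2000, d$N * d$L * rate))
  X <- matrix(1, 2000, 1, dimnames = list(NULL, "const"))
  cat <- toy_catalog(y, d$L, d$N)
  fit <- fit_bmr_gbm(X, cat, seed = 5)
  pred <- predict_expected(fit, X, cat)
  pooled <- sum(y) / sum(d$N * d$L)
  expect_true(all(abs(pred$yhat / (d$N * d$L) / pooled - 1) < 0.02))
})

test_that("GBM predictions are reproducible under a fixed seed", {
  d <- sim_design(800, 3, seed = 50)
  y <- withr::with_seed(51, rpois(800, d$N * d$L * 4e-6 * exp(0.5 * d$X[, 1])))
  cat <- toy_catalog(y, d$L, d$N)
  f1 <- fit_bmr_gbm(d$X, cat, seed = 77)
  f2 <- fit_bmr_gbm(d$X, cat, seed = 77)
  expect_identical(predict_expected(f1, d$X, cat)$yhat,
                   predict_expected(f2, d$X, cat)$yhat)
})

test_that("GBM importance is gain-normalised with max exactly 1", {
  d <- sim_design(1500, 3, seed = 60)
  y <- withr::with_seed(61, rpois(1500, d$N * d$L * 4e-6 * exp(0.8 * d$X[, 1])))
  fit <- fit_bmr_gbm(d$X, toy_catalog(y, d$L, d$N), seed = 3)
  imp <- gbm_importance(fit)
  expect_equal(sum(imp$gain), 1, tolerance = 1e-9)
  expect_equal(max(imp$normalized), 1)
  expect_equal(imp$feature[which.max(imp$normalized)], "f01")
})

test_that("prediction balance: total expected matches total observed", {
  # at the generator's study conditions, total expected counts on the
  # training elements stay within 2% of total observed for both models
  sim <- simulate_cohort(sim_config(n_elements = 200, n_train = 3000, seed = 72))
  cat <- suppressWarnings(count_mutations(sim$mutations, sim$training,
                                          donors = sim$donors))
  gbm <- fit_bmr_gbm(sim$X_train, cat, seed = 1)
  y <- cat$counts$y
  expect_equal(sum(predict_expected(gbm, sim$X_train, cat)$yhat) / sum(y), 1,
               tolerance = 0.02)
  Xs <- impute_and_scale(sim$X_train)$X
  glmfit <- fit_bmr_glm(Xs, cat)
  expect_equal(sum(predict_expected(glmfit, Xs, cat)$yhat) / sum(y), 1,
               tolerance = 0.02)
})

test_that("schema mismatches are refused at prediction time", {
  d <- sim_design(200, 2, seed = 80)
  y <- withr::with_seed(81, rpois(200, 1))
  cat <- toy_catalog(y, d$L, d$N)
  fit <- fit_bmr_gbm(d$X, cat, seed = 1)
  Xbad <- d$X
  colnames(Xbad) <- c("f01", "other")
  expect_error(predict_expected(fit, Xbad, cat), "schema")
})

test_that("cross-validation metrics match the closed-form definitions", {
  y <- c(1, 4, 2, 8, 5)
  yhat <- c(2, 3, 2, 7, 6)
  m <- driverscan:::.cv_metrics(y, yhat)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(unname(m[["R2"]]), 1 - ss_res / ss_tot)
  expect_equal(unname(m[["r"]]),
               sum((y - mean(y)) * (yhat - mean(yhat))) /
                 sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2)))
  expect_equal(unname(driverscan:::.cv_metrics(y, y)[["R2"]]), 1)
  expect_equal(suppressWarnings(
    unname(driverscan:::.cv_metrics(y, rep(mean(y), 5))[["R2"]])), 0)
})

test_that("evaluate_cv reports fold means and SEM in both modes", {
  d <- sim_design(1200, 2, seed = 90)
  y <- withr::with_seed(91, rpois(1200, d$N * d$L * 8e-6 * exp(0.6 * d$X[, 1])))
  cat <- toy_catalog(y, d$L, d$N)
  ev <- evaluate_cv("glm", impute_and_scale(d$X)$X, cat, k_folds = 5,
                    mode = "standard", seed = 2)
  expect_true(ev$R2 > 0 && ev$R2 < 1)
  expect_equal(nrow(ev$folds), 5)
  expect_true(ev$sem_R2 >= 0)
  ev_inv <- evaluate_cv("glm", impute_and_scale(d$X)$X, cat, k_folds = 5,
                        mode = "inverted", seed = 2)
  expect_true(ev_inv$pearson_r > 0.5)
})

test_that("fitted models round-trip through the on-disk format", {
  d <- sim_design(400, 2, seed = 95)
  y <- withr::with_seed(96, rpois(400, d$N * d$L * 4e-6 * exp(0.4 * d$X[, 1])))
  cat <- toy_catalog(y, d$L, d$N)
  p <- withr::local_tempfile(fileext = ".rds")

  gbm <- fit_bmr_gbm(d$X, cat, seed = 2)
  save_bmr_model(gbm, p)
  gbm2 <- load_bmr_model(p)
  expect_identical(predict_expected(gbm2, d$X, cat)$yhat,
                   predict_expected(gbm, d$X, cat)$yhat)

  glmfit <- fit_bmr_glm(d$X, cat)
  save_bmr_model(glmfit, p)
  expect_equal(load_bmr_model(p)$beta, glmfit$beta)
})
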