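test_that("balanced count is the geometric mean of y and n_d", {
  expect_equal(balanced_count(9, 4), 6)
  expect_equal(balanced_count(0, 0), 0)
  expect_equal(balanced_count(7, 7), 7)
  expect_equal(balanced_count(c(9, 0), c(4, 0)), c(6, 0))
  expect_error(balanced_count(-1, 2), "non-negative")
})

test_that("overdispersion test returns zero theta on equidispersed data", {
  yhat <- rep(5, 100)
  est <- suppressWarnings(test_overdispersion(yhat, yhat))  # y identical to yhat
  expect_equal(est$theta, 0)
  expect_gt(est$p_od, 0.5)
  expect_error(test_overdispersion(1:10, 1:10), ">= 30")
})

test_that("overdispersion test recovers NB2 theta", {
  set.seed(12)
  mu <- exp(rnorm(5000, log(5), 0.6))
  y <- rnbinom(5000, size = 1 / 0.5, mu = mu)
  est <- test_overdispersion(y, mu)
  expect_lt(est$p_od, 1e-6)
  expect_gt(est$theta, 0.35)
  expect_lt(est$theta, 0.65)
})

test_that("overdispersion rejection is near nominal under the Poisson null", {
  set.seed(13)
  rej <- 0L
  for (i in 1:200) {
    mu <- exp(rnorm(2000, log(4), 0.5))
    y <- rpois(2000, mu)
    rej <- rej + (test_overdispersion(y, mu)$p_od <= 0.01)
  }
  expect_lte(rej / 200, 0.05)  # loose bound; exact calibration checked at scale
})

test_that("burden p-values match finite-sum oracles on both branches", {
  expect_equal(burden_pvalue(0, yhat = 2, N = 10, L = 100), 1)

  # binomial branch: n = 10, rate 0.1, y_eff = 3
  oracle_binom <- 1 - sum(vapply(0:2, function(k) {
    choose(10, k) * 0.1^k * 0.9^(10 - k)
  }, 0))
  got <- burden_pvalue(3, yhat = 1, N = 1, L = 10)
  expect_equal(got, oracle_binom, tolerance = 1e-12)

  # NB branch: yhat = 2, s*theta = 0.5, y_eff = 5; direct NB2 pmf sum
  disp <- structure(list(theta = 0.5, p_od = 1e-4, s = 1),
                    class = "dispersion_estimate")
  r <- 1 / 0.5; mu <- 2
  pmf <- vapply(0:4, function(k) {
    exp(lgamma(k + r) - lgamma(r) - lfactorial(k)) *
      (r / (r + mu))^r * (mu / (r + mu))^k
  }, 0)
  got_nb <- burden_pvalue(5, yhat = 2, N = 100, L = 1000, disp = disp)
  expect_equal(got_nb, 1 - sum(pmf), tolerance = 1e-12)

  # theta truncated to zero degenerates to the Poisson tail
  disp0 <- structure(list(theta = 0, p_od = 1e-4, s = 1),
                     class = "dispersion_estimate")
  expect_equal(burden_pvalue(5, 2, 100, 1000, disp0),
               ppois(4, 2, lower.tail = FALSE))
})

test_that("the null dispatch honours the overdispersion switch", {
  disp_ns <- structure(list(theta = 0.5, p_od = 0.5, s = 1),
                       class = "dispersion_estimate")
  # p_od above od_cut -> binomial branch regardless of theta
  expect_equal(burden_pvalue(3, 1, 1, 10, disp_ns),
               burden_pvalue(3, 1, 1, 10, disp = NULL))
  # lymphoma scaling s = 3 widens the null
  d1 <- structure(list(theta = 0.3, p_od = 1e-3, s = 1),
                  class = "dispersion_estimate")
  d3 <- structure(list(theta = 0.3, p_od = 1e-3, s = 3),
                  class = "dispersion_estimate")
  expect_gt(burden_pvalue(10, 2, 100, 1000, d3),
            burden_pvalue(10, 2, 100, 1000, d1))
})

test_that("burden p-value is monotone in y_eff and in yhat", {
  p_up <- burden_pvalue(1:20, yhat = 3, N = 100, L = 1000)
  expect_true(all(diff(p_up) <= 0))
  p_mu <- vapply(seq(0.5, 8, by = 0.5), function(m) {
    burden_pvalue(6, m, 100, 1000)
  }, 0)
  expect_true(all(diff(p_mu) >= 0))
})

test_that("binomial and Poisson tails agree in the rare-event limit", {
  yhat <- 3
  NL <- 1e10
  pb <- burden_pvalue(7, yhat, N = 1e5, L = 1e5)
  pp <- ppois(6, yhat, lower.tail = FALSE)
  expect_lt(abs(pb - pp) / pp, 1e-6)
})

test_that("BH q-values reproduce the step-up oracle exactly", {
  expect_equal(bh_qvalues(0.03), 0.03)
  expect_equal(bh_qvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.04, 0.1)),
               c(0.04, 0.04, 4 * 0.04 / 3, 0.1))
  set.seed(14)
  for (n in c(7, 100, 1000)) {
    p <- runif(n)^2
    expect_equal(bh_qvalues(p), bf_bh(p), tolerance = 1e-14)
  }
})

test_that("significance engine gates the functional adjustment on raw cohort q", {
  set.seed(15)
  n <- 400
  L <- rep(5000, n)
  yhat <- rep(4, n)
  y <- rpois(n, 4)
  y[1] <- 30                       # clearly gated element
  n_d <- pmin(y, 50)
  cat <- toy_catalog(y, L, N = 50)
  cat$counts$n_d <- n_d
  pred <- data.table::data.table(element_id = cat$counts$element_id, yhat = yhat)

  imp_up <- data.table::data.table(element_id = cat$counts$element_id,
                                   S_combined = 30, w = 1.5)
  res_up <- run_significance(cat, pred, impacts = imp_up)
  gated <- res_up$q_cohort < 1 & res_up$y_f != res_up$y_b
  # ungated elements keep p_func identical to p_raw
  ungated <- res_up$y_f == res_up$y_b
  expect_equal(res_up$p_func[ungated], res_up$p_raw[ungated])
  # gated with w > 1 can only become more significant
  expect_true(all(res_up$p_func[!ungated] <= res_up$p_raw[!ungated]))
  expect_equal(res_up$y_f[1], 1.5 * res_up$y_b[1])

  imp_id <- data.table::data.table(element_id = cat$counts$element_id,
                                   S_combined = 20, w = 1)
  res_id <- run_significance(cat, pred, impacts = imp_id)
  expect_equal(res_id$p_func, res_id$p_raw)

  # missing predictions are refused with the offending ids
  expect_error(run_significance(cat, pred[-1], impacts = NULL), "missing")
})

test_that("untestable elements are carried through flagged, not tested", {
  cat <- toy_catalog(c(2, 0), c(1000, 0), N = 10)
  pred <- data.table::data.table(element_id = "e001", yhat = 1)
  res <- run_significance(cat, pred)
  expect_equal(nrow(res), 2)
  expect_equal(res$flag[res$element_id == "e002"], "untestable")
  expect_true(is.na(res$p_raw[res$element_id == "e002"]))
})

test_that("global correction re-runs BH across cohorts", {
  cat1 <- toy_catalog(c(9, 1), c(1000, 1000), N = 20)
  cat2 <- toy_catalog(c(1, 2), c(1000, 1000), N = 20)
  pred <- function(cat) data.table::data.table(element_id = cat$counts$element_id,
                                               yhat = 1.5)
  r1 <- run_significance(cat1, pred(cat1), cohort = "A")
  r2 <- run_significance(cat2, pred(cat2), cohort = "B")
  comb <- global_correction(list(r1, r2))
  expect_equal(nrow(comb), 4)
  expect_equal(comb$q_global, bh_qvalues(comb$p_func))
  # cohort q-values are untouched by the global step
  expect_equal(comb$q_cohort[comb$cohort == "A"], r1$q_cohort)
})
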