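#' @title Burden significance testing
#'
#' @description Each element's balanced mutation count y_b = sqrt(y * n_d)
#' (geometric mean of mutation and mutated-donor counts, damping single-donor
#' hypermutation) is compared to the BMR model's expected count under a
#' binomial null, or a negative-binomial null when a regression-based
#' overdispersion test on the training set rejects equidispersion. Nearly
#' significant elements (cohort q < 0.25) have their counts multiplied by the
#' functional weight w and are re-tested; global q-values define the final
#' driver list (q < 0.1).
#'
#' @name significance
NULL

#' Balanced mutation count
#'
#' Geometric mean of the mutation count and the mutated-donor count.
#'
#' @param y observed mutation count (>= 0)
#' @param n_d number of distinct mutated donors (>= 0)
#' @return sqrt(y * n_d), vectorized
#' @export
balanced_count <- function(y, n_d) {
  if (any(y < 0) || any(n_d < 0)) stop("counts must be non-negative")
  sqrt(y * n_d)
}

#' Regression-based overdispersion test
#'
#' Cameron-Trivedi auxiliary regression for the NB2 alternative
#' Var(y) = mu + theta * mu^2: the statistic
#' z_i = ((y_i - yhat_i)^2 - y_i) / yhat_i is regressed on yhat_i through the
#' origin; the slope estimates theta (truncated at 0) and a one-sided t-test
#' of slope > 0 gives the overdispersion p-value. Run on the training set of
#' each cohort.
#'
#' @param y observed counts
#' @param yhat expected counts (> 0; elements with yhat <= 0 are dropped)
#' @param s cohort scaling factor for theta carried into the null
#'   (3 for lymphomas, 1 otherwise)
#' @return object of class `dispersion_estimate`: list(theta, p_od, s, slope,
#'   n_used)
#' @export
test_overdispersion <- function(y, yhat, s = 1) {
  keep <- yhat > 0
  y <- y[keep]; yhat <- yhat[keep]
  if (length(y) < 30) stop("overdispersion test needs >= 30 elements with yhat > 0")
  z <- ((y - yhat)^2 - y) / yhat
  fit <- lm(z ~ 0 + yhat)
  slope <- unname(coef(fit)[1])
  se <- sqrt(vcov(fit)[1, 1])
  tval <- slope / se
  p_od <- pt(tval, df = fit$df.residual, lower.tail = FALSE)
  structure(list(theta = max(slope, 0), p_od = p_od, s = s, slope = slope,
                 n_used = length(y)), class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("dispersion_estimate: theta = %.4g (s = %g), p_od = %.3g over %d elements\n",
              x$theta, x$s, x$p_od, x$n_used))
  invisible(x)
}

#' Upper-tail burden p-value
#'
#' p = P(Y >= ceiling(y_eff)) with p = 1 when y_eff = 0. The null is
#' NB2(mean yhat, dispersion s * theta) when the overdispersion test rejects
#' (p_od <= od_cut), otherwise Binomial(n = round(N * L), p = yhat / (N * L)).
#' Tails are computed through the stable incomplete-beta/gamma routines, so
#' n up to 1e10 needs no enumeration; when s * theta = 0 the NB null
#' degenerates to Poisson.
#'
#' @param y_eff effective (possibly non-integer) count: y_b or y_f
#' @param yhat expected count under the BMR model (> 0)
#' @param N cohort donor count
#' @param L effective element length (bp)
#' @param disp a `dispersion_estimate` (or NULL for the binomial null)
#' @param od_cut overdispersion-test significance switch (default 0.01)
#' @return p-value(s) in [0,1]; vectorized over y_eff, yhat, L
#' @export
burden_pvalue <- function(y_eff, yhat, N, L, disp = NULL, od_cut = 0.01) {
  stopifnot(all(yhat > 0), all(L > 0))
  k <- ceiling(y_eff)
  use_nb <- !is.null(disp) && disp$p_od <= od_cut
  if (use_nb) {
    stheta <- disp$s * disp$theta
    p <- if (stheta > 0) {
      pnbinom(k - 1, size = 1 / stheta, mu = yhat, lower.tail = FALSE)
    } else {
      ppois(k - 1, lambda = yhat, lower.tail = FALSE)
    }
  } else {
    n <- round(N * L)
    rate <- yhat / (N * L)
    if (any(rate >= 1)) stop("expected count reaches N * L under the binomial null")
    p <- pbinom(k - 1, size = n, prob = rate, lower.tail = FALSE)
  }
  ifelse(y_eff <= 0, 1, pmin(p, 1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of m * p_(j) / j, returned
#' in the original order.
#'
#' @param p vector of p-values in [0,1]
#' @return vector of q-values in [0,1]
#' @export
bh_qvalues <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Configuration of the functional adjustment and significance thresholds
#'
#' @param F assumed fraction of functionally relevant variants among all
#'   observed variants, in (0,1); the threshold score is
#'   S_T = -10*log10(F) (default F = 0.01, S_T = 20)
#' @param q_gate nearly-significant gate on the raw cohort q-value
#'   (default 0.25): only gated elements receive the functional adjustment
#' @param q_sig significance level on the global q-value (default 0.1)
#' @param od_cut p-value switch of the overdispersion test (default 0.01)
#' @return list of class `adjustment_config`
#' @export
adjustment_config <- function(F = 0.01, q_gate = 0.25, q_sig = 0.1,
                              od_cut = 0.01) {
  stopifnot(F > 0, F < 1, q_sig > 0, q_sig < q_gate, q_gate < 1)
  structure(list(F = F, S_T = threshold_score(F), q_gate = q_gate,
                 q_sig = q_sig, od_cut = od_cut), class = "adjustment_config")
}

#' Burden test with functional adjustment and multiple-testing correction
#'
#' The significance engine: (1) raw p-values from balanced counts
#' y_b = sqrt(y * n_d); (2) cohort-wise BH correction; (3) elements with raw
#' cohort q below `q_gate` get the functionally adjusted count y_f = w * y_b
#' and a recomputed p-value, all others keep p_func = p_raw; (4) BH at cohort
#' scope and globally across all rows; an element is significant when its
#' global q-value is below `q_sig`.
#'
#' @param catalog a `mutation_catalog`
#' @param prediction data.table `element_id`, `yhat` from
#'   [predict_expected()]
#' @param disp a `dispersion_estimate` from the cohort's training set (or
#'   NULL to force the binomial null)
#' @param impacts optional `element_impact` table supplying the functional
#'   weight `w` (and `S_combined`); elements without impact get w = 1
#' @param cfg an [adjustment_config()]
#' @param set_name element-set label echoed in the output
#' @param cohort cohort label; when testing several cohorts, bind their
#'   catalogs with distinct labels and BH runs per cohort and globally
#' @return data.table with columns `element_id`, `set`, `cohort`, `y`,
#'   `n_d`, `L`, `yhat`, `S_combined`, `w`, `y_b`, `y_f`, `p_raw`, `p_func`,
#'   `q_cohort`, `q_global`, `flag` ("significant", "nearly_significant",
#'   "ns", or "untestable")
#' @export
run_significance <- function(catalog, prediction, disp = NULL, impacts = NULL,
                             cfg = adjustment_config(), set_name = "elements",
                             cohort = "cohort1") {
  ct <- .catalog_table(catalog)
  res <- merge(ct, data.table::as.data.table(prediction)[, .(element_id, yhat)],
               by = "element_id", all.x = TRUE, sort = FALSE)
  if (anyNA(res$yhat)) {
    stop("elements missing a BMR prediction: ",
         paste(head(res$element_id[is.na(res$yhat)], 5), collapse = ", "))
  }
  res[, `:=`(set = set_name, cohort = cohort)]
  if (!is.null(impacts)) {
    res <- merge(res,
                 data.table::as.data.table(impacts)[, .(element_id, S_combined, w)],
                 by = "element_id", all.x = TRUE, sort = FALSE)
    res[is.na(w), w := 1]
  } else {
    res[, `:=`(S_combined = NA_real_, w = 1)]
  }
  res[, y_b := balanced_count(y, n_d)]
  res[, p_raw := burden_pvalue(y_b, yhat, catalog$N, L, disp, cfg$od_cut)]
  res[, q_raw := bh_qvalues(p_raw), by = cohort]
  res[, gated := q_raw < cfg$q_gate]
  res[, y_f := ifelse(gated, w * y_b, y_b)]
  res[, p_func := p_raw]
  res[gated == TRUE,
      p_func := burden_pvalue(y_f, yhat, catalog$N, L, disp, cfg$od_cut)]
  res[, q_cohort := bh_qvalues(p_func), by = cohort]
  res[, q_global := bh_qvalues(p_func)]
  res[, flag := data.table::fcase(
    q_global < cfg$q_sig, "significant",
    q_global < cfg$q_gate, "nearly_significant",
    default = "ns")]
  untest <- catalog$counts[L <= 0]
  if (nrow(untest)) {
    pad <- data.table::data.table(element_id = untest$element_id,
                                  y = untest$y, n_d = untest$n_d, L = untest$L,
                                  set = set_name, cohort = cohort,
                                  flag = "untestable")
    res <- rbind(res, pad, fill = TRUE)
  }
  cols <- c("element_id", "set", "cohort", "y", "n_d", "L", "yhat",
            "S_combined", "w", "y_b", "y_f", "p_raw", "p_func",
            "q_cohort", "q_global", "flag")
  res[, .SD, .SDcols = cols]
}

#' Re-correct significance across several cohorts
#'
#' Cohort q-values gate the functional adjustment inside each cohort run;
#' the final driver list uses q-values corrected across all cohorts. Bind
#' per-cohort result tables and recompute the global BH correction and
#' significance flags.
#'
#' @param res_list list of tables from [run_significance()] (one per cohort)
#' @param cfg an [adjustment_config()]
#' @return combined data.table with refreshed `q_global` and `flag`
#' @export
global_correction <- function(res_list, cfg = adjustment_config()) {
  res <- data.table::rbindlist(res_list, fill = TRUE)
  testable <- res$flag != "untestable"
  res[testable, q_global := bh_qvalues(p_func)]
  res[testable, flag := data.table::fcase(
    q_global < cfg$q_sig, "significant",
    q_global < cfg$q_gate, "nearly_significant",
    default = "ns")]
  res[]
}

#' Write the result table as TSV
#' @param res table from [run_significance()]
#' @param path output path
#' @export
write_results_tsv <- function(res, path) {
  data.table::fwrite(res, path, sep = "\t")
  invisible(path)
}
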